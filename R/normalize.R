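#' Select the reference gel of a gel set
#'
#' The reference is the gel that best represents the experiment: the gel
#' with the greatest number of nonzero spot volumes wins; ties are broken
#' by the highest median Spearman correlation of log-volumes with all
#' other gels, remaining ties by lexicographic gel id.
#'
#' @param x a [gelset()].
#' @return the reference gel id (character scalar).
#' @export
select_reference_gel <- function(x) {
  stopifnot(inherits(x, "gelset"))
  v <- x$volumes
  if (ncol(v) == 0) stop("gelset has no gels", call. = FALSE)
  if (ncol(v) == 1) return(colnames(v))
  nz <- colSums(v > 0)
  cand <- which(nz == max(nz))
  if (length(cand) > 1) {
    # Spearman via per-gel ranks of log-volumes (zeros excluded as NA);
    # one cor() call instead of a quadratic pairwise loop
    lv <- log(v)
    lv[!is.finite(lv)] <- NA
    rk <- apply(lv, 2L, rank, na.last = "keep")
    cc <- suppressWarnings(stats::cor(rk, use = "pairwise.complete.obs"))
    diag(cc) <- NA
    med <- apply(cc[, cand, drop = FALSE], 2L, stats::median, na.rm = TRUE)
    cand <- cand[med >= max(med) - 1e-12]
  }
  sort(colnames(v)[cand])[1L]
}

#' Per-gel bias (gain) factor against a reference gel
#'
#' Multiplicative gel-to-gel differences in load and scan gain shift every
#' spot of a gel by a common factor.  Assuming most spots do not change,
#' the bias is estimated from the mean log spot-ratio to the reference:
#' `gain = exp(-mean(log(gel / reference)))` over spots positive in both
#' gels, so that after scaling the mean log-ratio is zero.
#'
#' @param gel,reference aligned numeric vectors of spot volumes.
#' @param trim fraction trimmed from each tail of the log-ratios before
#'   averaging (`0` = plain mean; a robust option when a sizeable spot
#'   subset does change).
#' @return the gain factor (positive scalar).
#' @export
compute_bias_factor <- function(gel, reference, trim = 0) {
  if (length(gel) != length(reference)) {
    stop("gel and reference must be aligned on the same spots", call. = FALSE)
  }
  common <- gel > 0 & reference > 0
  if (sum(common) < 3) {
    stop("fewer than 3 spots positive in both gels; bias factor is under-determined",
         call. = FALSE)
  }
  lr <- log(gel[common] / reference[common])
  exp(-mean(lr, trim = trim))
}

#' Normalize a gel set by per-gel bias factors
#'
#' Selects a reference gel (see [select_reference_gel()]), computes one
#' gain factor per gel against it and rescales all spot volumes, so that
#' each gel's mean log spot-ratio to the reference is zero.  All channels
#' and groups are normalized against the single common reference.
#'
#' @param x a raw [gelset()].
#' @param reference_gel optional gel id to use as reference instead of the
#'   automatic choice.
#' @inheritParams compute_bias_factor
#' @return the normalized `gelset`; per-gel gains are attached as the
#'   `bias_factors` attribute (data.frame `gel_id`, `gain`).
#' @export
normalize_gelset <- function(x, reference_gel = NULL, trim = 0) {
  stopifnot(inherits(x, "gelset"))
  if (x$normalized) {
    stop("gelset is already normalized", call. = FALSE)
  }
  ref <- if (is.null(reference_gel)) select_reference_gel(x) else reference_gel
  if (!ref %in% colnames(x$volumes)) {
    stop("reference gel '", ref, "' not present in gelset", call. = FALSE)
  }
  refv <- x$volumes[, ref]
  gains <- vapply(colnames(x$volumes), function(g) {
    tryCatch(compute_bias_factor(x$volumes[, g], refv, trim = trim),
             error = function(e) {
               stop("normalization failed for gel '", g, "': ",
                    conditionMessage(e), call. = FALSE)
             })
  }, numeric(1))
  out <- x
  out$volumes <- sweep(x$volumes, 2L, gains, `*`)
  out$normalized <- TRUE
  out$reference_gel <- ref
  attr(out, "bias_factors") <- data.frame(gel_id = colnames(x$volumes),
                                          gain = unname(gains),
                                          stringsAsFactors = FALSE)
  out
}
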