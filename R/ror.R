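# Ratio-of-ratios quantification.
#
# Two ratios are formed per spot from normalized volumes:
#   delta abundance = Asc+ HF / Asc+ NH   (protein amount change)
#   delta S-NO      = Asc- HF / Asc- NH   (reactive-thiol signal change)
# and their quotient, the ratio of ratios
#   RoR = delta S-NO / delta abundance
# isolates the S-NO occupancy change from the abundance change.  Because
# nitrosylation blocks dye binding, a *negative* RoR (fold convention)
# means *increased* S-NO in HF, and vice versa.

# per-spot mean of log2 volumes for one group/channel cell; zeros are
# excluded (log undefined), spots with no positive volume give NA
.group_log2_mean <- function(x, group, channel) {
  gels <- .gels_for(x, group = group, channel = channel)
  if (length(gels) < 2) {
    stop("need >= 2 gels for group ", group, ", channel ", channel, call. = FALSE)
  }
  v <- x$volumes[, gels, drop = FALSE]
  lv <- log2(v)
  lv[!is.finite(lv)] <- NA
  n <- rowSums(!is.na(lv))
  m <- rowMeans(lv, na.rm = TRUE)
  m[n == 0] <- NA
  m
}

#' HF/NH group ratio of normalized spot volumes
#'
#' The group summary is the geometric mean (mean of log2 volumes,
#' back-transformed), so ratios compose exactly with the log-scale tests
#' downstream.
#'
#' @param x a normalized [gelset()].
#' @param spot spot id.
#' @param channel `"Asc+"` (abundance) or `"Asc-"` (S-NO signal).
#' @return the HF/NH ratio as a signed fold value.
#' @export
group_ratio <- function(x, spot, channel = c("Asc+", "Asc-")) {
  channel <- match.arg(channel)
  stopifnot(inherits(x, "gelset"))
  if (!x$normalized) stop("gelset must be normalized first", call. = FALSE)
  if (!spot %in% rownames(x$volumes)) {
    stop("unknown spot id '", spot, "'", call. = FALSE)
  }
  m_hf <- .group_log2_mean(x, "HF", channel)[spot]
  m_nh <- .group_log2_mean(x, "NH", channel)[spot]
  if (is.na(m_hf) || is.na(m_nh)) {
    stop("ratio undefined for spot '", spot, "' (all-zero group mean)", call. = FALSE)
  }
  unname(linear_to_fold(2^(m_hf - m_nh)))
}

#' Ratio of ratios from two fold values
#'
#' @param delta_sno HF/NH S-NO signal change (Asc- channel), signed fold.
#' @param delta_abundance HF/NH abundance change (Asc+ channel), signed fold.
#' @return `delta_sno / delta_abundance` in linear arithmetic, reported as
#'   a signed fold value.  Vectorized.
#' @examples
#' compute_ror(-2.02, 2.50)  # -5.05: strong S-NO increase
#' @export
compute_ror <- function(delta_sno, delta_abundance) {
  linear_to_fold(fold_to_linear(delta_sno) / fold_to_linear(delta_abundance))
}

#' Direction call for the S-NO change
#'
#' S-NO modification quenches the dye signal, so the sign convention is
#' inverted: RoR at or below `-threshold` is called `increased` S-NO, at
#' or above `+threshold` `decreased`, otherwise `unchanged`.
#'
#' @param ror signed fold RoR value(s).
#' @param threshold positive fold threshold (`>= 1`), default 1.5.
#' @return character vector in `{increased, decreased, unchanged}`.
#' @export
call_sno_direction <- function(ror, threshold = 1.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 1) {
    stop("threshold must be a single fold value >= 1", call. = FALSE)
  }
  out <- rep("unchanged", length(ror))
  out[ror <= -threshold] <- "increased"
  out[ror >= threshold] <- "decreased"
  out
}

#' Per-spot RoR table for a normalized gel set
#'
#' @param x a normalized [gelset()].
#' @param threshold fold threshold for the direction call.
#' @return data.frame with one row per spot: `spot_id`,
#'   `delta_abundance`, `delta_sno`, `ror` (signed folds; NA where a
#'   group mean is undefined) and `sno_call`.
#' @export
ror_quantify <- function(x, threshold = 1.5) {
  stopifnot(inherits(x, "gelset"))
  if (!x$normalized) stop("gelset must be normalized first", call. = FALSE)
  d_ab_log2 <- .group_log2_mean(x, "HF", "Asc+") - .group_log2_mean(x, "NH", "Asc+")
  d_sno_log2 <- .group_log2_mean(x, "HF", "Asc-") - .group_log2_mean(x, "NH", "Asc-")
  to_fold <- function(l2) ifelse(is.na(l2), NA_real_, linear_to_fold(2^ifelse(is.na(l2), 0, l2)))
  delta_abundance <- to_fold(d_ab_log2)
  delta_sno <- to_fold(d_sno_log2)
  ok <- !is.na(delta_abundance) & !is.na(delta_sno)
  ror <- rep(NA_real_, nrow(x$volumes))
  ror[ok] <- compute_ror(delta_sno[ok], delta_abundance[ok])
  sno_call <- rep(NA_character_, length(ror))
  sno_call[ok] <- call_sno_direction(ror[ok], threshold)
  data.frame(spot_id = rownames(x$volumes),
             delta_abundance = delta_abundance,
             delta_sno = delta_sno,
             ror = ror, sno_call = sno_call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Packaged spot-profile reference table
#'
#' A transcription of the published table of 147 differential PBMC
#' protein spots: spot id, pI, molecular weight, protein/gene annotation,
#' and the printed NH and HF Asc-/Asc+ subcolumns, HF-vs-NH abundance
#' fold and HF-vs-NH RoR.  Used as a deterministic verification fixture
#' for the RoR arithmetic (see [verify_table_fixture()]).
#'
#' @param path optional path to an alternative fixture TSV with the same
#'   columns.
#' @return data.frame with columns `spot_id`, `pI`, `MW_kDa`, `protein`,
#'   `gene`, `accession`, `delta_sno_NH`, `delta_sno_HF`,
#'   `abundance_HF_vs_NH`, `ror_HF_vs_NH`.
#' @export
reference_spot_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_spot_profile.tsv", package = "snoRoR",
                        mustWork = TRUE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# linear-ratio interval compatible with a printed fold value rounded to
# `digits` decimals; folds in (-1, 1) do not exist, so intervals are
# clamped at the +/-1 boundary
.fold_linear_interval <- function(f, digits = 2) {
  eps <- 0.5 * 10^(-digits)
  lo <- f - eps
  hi <- f + eps
  if (f >= 1) lo <- max(lo, 1)
  if (f <= -1) hi <- min(hi, -1)
  ext <- function(x) if (x >= 1) x else if (x <= -1) -1 / x else 1
  c(ext(lo), ext(hi))
}

#' Verify the printed RoR arithmetic of the fixture table
#'
#' For every fixture row the RoR is recomputed from the printed HF S-NO
#' fold and abundance fold.  Printed inputs are themselves rounded to two
#' decimals, so each row is checked by interval arithmetic: the printed
#' RoR must lie within the fold interval induced by +/-0.005 rounding of
#' each input, expanded by +/-0.005 output rounding.  Column extrema are
#' reported alongside.
#'
#' @param fixture a fixture data.frame, by default [reference_spot_table()].
#' @param digits printed precision of the table (decimal places).
#' @return an object of class `table_verification`: a list with `rows`
#'   (per-row recomputation, interval bounds and pass flag), `pass_rate`
#'   (fraction of rows passing), and `extrema` (max/min of the abundance
#'   and RoR columns).
#' @export
verify_table_fixture <- function(fixture = reference_spot_table(), digits = 2) {
  need <- c("spot_id", "delta_sno_HF", "abundance_HF_vs_NH", "ror_HF_vs_NH")
  miss <- setdiff(need, names(fixture))
  if (length(miss)) {
    stop("fixture is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(fixture)
  rec <- lo <- hi <- numeric(n)
  eps <- 0.5 * 10^(-digits)
  for (i in seq_len(n)) {
    sno <- fixture$delta_sno_HF[i]
    ab <- fixture$abundance_HF_vs_NH[i]
    if (!is.finite(sno) || !is.finite(ab) || abs(sno) < 1 || abs(ab) < 1) {
      stop("malformed fixture row for spot '", fixture$spot_id[i], "'",
           call. = FALSE)
    }
    rec[i] <- compute_ror(sno, ab)
    si <- .fold_linear_interval(sno, digits)
    ai <- .fold_linear_interval(ab, digits)
    lo[i] <- linear_to_fold(si[1L] / ai[2L]) - eps
    hi[i] <- linear_to_fold(si[2L] / ai[1L]) + eps
  }
  printed <- fixture$ror_HF_vs_NH
  rows <- data.frame(spot_id = fixture$spot_id,
                     delta_sno = fixture$delta_sno_HF,
                     delta_abundance = fixture$abundance_HF_vs_NH,
                     ror_printed = printed,
                     ror_recomputed = rec,
                     ror_lo = lo, ror_hi = hi,
                     pass = printed >= lo & printed <= hi,
                     stringsAsFactors = FALSE)
  structure(list(
    rows = rows,
    pass_rate = mean(rows$pass),
    extrema = list(abundance_max = max(fixture$abundance_HF_vs_NH),
                   abundance_min = min(fixture$abundance_HF_vs_NH),
                   ror_max = max(printed),
                   ror_min = min(printed))),
    class = "table_verification")
}

#' @export
print.table_verification <- function(x, ...) {
  cat(sprintf("fixture verification: %d/%d rows within rounding interval (%.1f%%)\n",
              sum(x$rows$pass), nrow(x$rows), 100 * x$pass_rate))
  e <- x$extrema
  cat(sprintf("abundance fold range: %.2f to %.2f; RoR range: %.2f to %.2f\n",
              e$abundance_min, e$abundance_max, e$ror_min, e$ror_max))
  if (any(!x$rows$pass)) {
    cat("failing spots:", paste(x$rows$spot_id[!x$rows$pass], collapse = ", "), "\n")
  }
  invisible(x)
}
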