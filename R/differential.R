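#' Per-group summary statistics for a spot
#'
#' @param values numeric vector of (typically log2) spot volumes for one
#'   group; at least 2 finite values required.
#' @return named vector `c(mean, sd, cov)` with the sample SD (n-1
#'   denominator) and `cov = sd / |mean|`.
#' @export
spot_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop("need >= 2 finite values to compute spot statistics", call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  c(mean = m, sd = s, cov = s / abs(m))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value.  Degenerate inputs follow fixed
#' conventions: zero variance in both groups with equal means gives
#' `p = 1`; zero variance with unequal means gives the smallest
#' representable p with a warning.
#'
#' @param a,b numeric vectors, at least 2 values each.
#' @return list with elements `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("need >= 2 values per group", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  dm <- mean(a) - mean(b)
  if (se2 == 0) {
    if (dm == 0) return(list(t = 0, df = na + nb - 2, p = 1))
    warning("zero variance with unequal means; p-value degenerates to 0")
    return(list(t = sign(dm) * Inf, df = na + nb - 2, p = .Machine$double.xmin))
  }
  t <- dm / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# vectorized Welch across the rows of two matrices (spots x gels);
# NA entries are ignored per row, rows with < 2 values per group give NA
.welch_rows <- function(A, B) {
  cnt <- function(M) rowSums(!is.na(M))
  rmean <- function(M) rowMeans(M, na.rm = TRUE)
  rvar <- function(M, m, n) {
    v <- rowSums((M - m)^2, na.rm = TRUE) / (n - 1)
    v[n < 2] <- NA
    v
  }
  na <- cnt(A); nb <- cnt(B)
  ma <- rmean(A); mb <- rmean(B)
  va <- rvar(A, ma, na); vb <- rvar(B, mb, nb)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- !is.na(se2) & se2 == 0
  if (any(zero)) {
    eq <- zero & (ma == mb)
    t[eq] <- 0; df[eq] <- (na + nb - 2)[eq]; p[eq] <- 1
    ne <- zero & (ma != mb)
    if (any(ne)) {
      warning("zero variance with unequal means for ", sum(ne),
              " spot(s); p degenerates to 0")
      t[ne] <- sign(ma - mb)[ne] * Inf
      df[ne] <- (na + nb - 2)[ne]
      p[ne] <- .Machine$double.xmin
    }
  }
  bad <- na < 2 | nb < 2
  t[bad] <- NA; df[bad] <- NA; p[bad] <- NA
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb,
       sd_a = sqrt(va), sd_b = sqrt(vb), n_a = na, n_b = nb)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted
#' ascending, `q_(i) = min_{j >= i} p_(j) * m / j`, returned in the
#' original order and capped at 1.
#'
#' @param pvalues numeric vector with values in `(0, 1]`.
#' @return the adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || length(pvalues) == 0) {
    stop("'pvalues' must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- !is.finite(pvalues) | pvalues <= 0 | pvalues > 1
  if (any(bad)) {
    stop("p-values must lie in (0, 1] (offending value: ",
         pvalues[which(bad)[1L]], ")", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Named significance presets
#'
#' `discovery` is the spot-selection rule used ahead of identification
#' (`|fold| >= 1.5`, BH-adjusted `p < 0.05`); `mars_input` is the
#' stricter screen used to assemble classifier features
#' (`|fold| >= 1.5`, BH-adjusted `p < 0.001`).
#'
#' @param preset `"discovery"` or `"mars_input"`.
#' @return list with `fold_threshold`, `alpha`, `use_adjusted`.
#' @export
differential_preset <- function(preset = c("discovery", "mars_input")) {
  preset <- match.arg(preset)
  switch(preset,
         discovery = list(fold_threshold = 1.5, alpha = 0.05, use_adjusted = TRUE),
         mars_input = list(fold_threshold = 1.5, alpha = 0.001, use_adjusted = TRUE))
}

#' Spot-wise differential statistics for one channel
#'
#' For each spot: per-group mean/SD/CoV, the HF/NH fold (geometric-mean
#' ratio, signed fold convention), the Welch t-test on log2 volumes and
#' its BH-adjusted q-value (the multiple-testing family is the set of
#' spots with a defined test), plus a significance flag under the
#' configured rule.  CoV is computed on raw-scale volumes, where a
#' coefficient of variation is well defined; mean and SD are reported on
#' the log2 scale used by the test.
#'
#' @param x a normalized [gelset()].
#' @param channel `"Asc+"` or `"Asc-"`.
#' @param fold_threshold minimum `|fold|` for significance.
#' @param alpha significance level.
#' @param use_adjusted if `TRUE` the BH q-value is compared to `alpha`,
#'   otherwise the raw p-value.
#' @return data.frame, one row per spot.
#' @export
differential_table <- function(x, channel = c("Asc+", "Asc-"),
                               fold_threshold = 1.5, alpha = 0.05,
                               use_adjusted = TRUE) {
  channel <- match.arg(channel)
  stopifnot(inherits(x, "gelset"))
  if (!x$normalized) stop("gelset must be normalized first", call. = FALSE)
  gels_hf <- .gels_for(x, "HF", channel)
  gels_nh <- .gels_for(x, "NH", channel)
  if (length(gels_hf) < 2 || length(gels_nh) < 2) {
    stop("need >= 2 gels per group in channel ", channel, call. = FALSE)
  }
  raw_hf <- x$volumes[, gels_hf, drop = FALSE]
  raw_nh <- x$volumes[, gels_nh, drop = FALSE]
  l2 <- function(M) { M <- log2(M); M[!is.finite(M)] <- NA; M }
  A <- l2(raw_hf); B <- l2(raw_nh)
  w <- .welch_rows(A, B)
  fold <- rep(NA_real_, nrow(A))
  ok <- !is.na(w$mean_a) & !is.na(w$mean_b) & w$n_a > 0 & w$n_b > 0
  fold[ok] <- linear_to_fold(2^(w$mean_a[ok] - w$mean_b[ok]))
  q <- rep(NA_real_, length(w$p))
  tested <- !is.na(w$p)
  if (any(tested)) q[tested] <- bh_adjust(w$p[tested])
  raw_cov <- function(M) {
    m <- rowMeans(M)
    s <- sqrt(rowSums((M - m)^2) / (ncol(M) - 1))
    s / abs(m)
  }
  crit_p <- if (use_adjusted) q else w$p
  significant <- !is.na(fold) & !is.na(crit_p) &
    abs(fold) >= fold_threshold & crit_p < alpha
  data.frame(spot_id = rownames(x$volumes),
             mean_NH = w$mean_b, sd_NH = w$sd_b, cov_NH = raw_cov(raw_nh),
             mean_HF = w$mean_a, sd_HF = w$sd_a, cov_HF = raw_cov(raw_hf),
             fold = fold, welch_t = w$t, welch_df = w$df,
             p = w$p, q = q, significant = significant,
             direction = ifelse(is.na(fold), NA_character_,
                                ifelse(fold >= 1, "up", "down")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select differential spots by fold and p thresholds
#'
#' A spot passes iff `|fold| >= fold_threshold` and the configured
#' p-value (raw or BH-adjusted) is below `alpha`.  Lowering `alpha` or
#' raising `fold_threshold` never adds a spot.
#'
#' @param stats a [differential_table()] result.
#' @inheritParams differential_table
#' @return the selected subset of `stats`, with the `significant` column
#'   recomputed under the supplied thresholds.
#' @export
select_spots <- function(stats, fold_threshold = 1.5, alpha = 0.05,
                         use_adjusted = TRUE) {
  crit_p <- if (use_adjusted) stats$q else stats$p
  keep <- !is.na(stats$fold) & !is.na(crit_p) &
    abs(stats$fold) >= fold_threshold & crit_p < alpha
  out <- stats[keep, , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Select differentially S-NO-modified spots
#'
#' The S-NO selection combines the two quantities the dual-channel design
#' provides: the fold criterion is applied to the abundance-normalized
#' RoR (so a mere abundance change does not masquerade as an S-NO
#' change), while the p criterion comes from the Welch test on the Asc-
#' channel.  The direction label is the RoR direction call.
#'
#' @param sno_stats a [differential_table()] for the `"Asc-"` channel.
#' @param ror a [ror_quantify()] table on the same spots.
#' @inheritParams differential_table
#' @return the selected rows of `sno_stats` with `ror` and `sno_call`
#'   columns appended.
#' @export
select_sno_spots <- function(sno_stats, ror, fold_threshold = 1.5,
                             alpha = 0.05, use_adjusted = TRUE) {
  m <- match(sno_stats$spot_id, ror$spot_id)
  if (anyNA(m)) {
    stop("spot '", sno_stats$spot_id[which(is.na(m))[1L]],
         "' absent from the RoR table", call. = FALSE)
  }
  r <- ror$ror[m]
  crit_p <- if (use_adjusted) sno_stats$q else sno_stats$p
  keep <- !is.na(r) & !is.na(crit_p) &
    abs(r) >= fold_threshold & crit_p < alpha
  out <- sno_stats[keep, , drop = FALSE]
  out$ror <- r[keep]
  out$sno_call <- call_sno_direction(out$ror, fold_threshold)
  out$significant <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Venn classification of abundance- and S-NO-selected spots
#'
#' @param abundance_selected,sno_selected character vectors of spot ids.
#' @return list with counts `both`, `abundance_only`, `sno_only` and the
#'   corresponding id vectors.
#' @export
venn_classify <- function(abundance_selected, sno_selected) {
  a <- unique(as.character(abundance_selected))
  s <- unique(as.character(sno_selected))
  both <- intersect(a, s)
  list(both = length(both),
       abundance_only = length(setdiff(a, s)),
       sno_only = length(setdiff(s, a)),
       ids = list(both = both,
                  abundance_only = setdiff(a, s),
                  sno_only = setdiff(s, a)))
}
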