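#' Signed fold convention
#'
#' Differential gel analysis reports ratios in a signed "fold" convention:
#' a positive linear ratio `r >= 1` is reported as `r`, while `r < 1` is
#' reported as `-1/r` (so e.g. a halving is `-2.00`, never `0.5`).  Every
#' fold value therefore satisfies `|f| >= 1`, with `1` the neutral value.
#' The two maps are exact inverses for all positive reals.
#'
#' @param r positive linear ratio(s).
#' @param f signed fold value(s) with `|f| >= 1`.
#' @return `linear_to_fold()` returns signed fold values; `fold_to_linear()`
#'   returns positive linear ratios.
#' @examples
#' linear_to_fold(c(2, 1, 0.5))   # 2, 1, -2
#' fold_to_linear(-1.88)          # 0.5319149
#' @export
linear_to_fold <- function(r) {
  if (!is.numeric(r) || length(r) == 0) {
    stop("'r' must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- !is.finite(r) | r <= 0
  if (any(bad)) {
    stop("linear ratios must be positive and finite (offending value: ",
         r[which(bad)[1L]], ")", call. = FALSE)
  }
  ifelse(r >= 1, r, -1 / r)
}

#' @rdname linear_to_fold
#' @export
fold_to_linear <- function(f) {
  if (!is.numeric(f) || length(f) == 0) {
    stop("'f' must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- !is.finite(f) | abs(f) < 1
  if (any(bad)) {
    stop("fold values must be finite with |f| >= 1 (offending value: ",
         f[which(bad)[1L]], ")", call. = FALSE)
  }
  ifelse(f >= 1, f, -1 / f)
}
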