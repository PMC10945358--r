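#' Pearson correlation with a two-sided p-value
#'
#' Computes the Pearson correlation coefficient between two numeric vectors
#' together with a two-sided p-value from the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom. Pairs
#' with missing values are dropped. This is the single correlation routine
#' shared by every stage of the pipeline (trait correlations, module-trait
#' associations, GS and MM), so all reported r/p pairs are computed
#' identically.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with elements `r`, `p` and `n` (complete pairs used). If
#'   fewer than 3 complete pairs remain, or either vector is constant, `r`
#'   and `p` are `NA_real_` (a not-computable result, not an error).
#' @examples
#' pearson_with_p(1:10, (1:10)^2)
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  # guard |r| = 1: t is infinite, p underflows to 0
  if (abs(r) >= 1) {
    return(list(r = sign(r), p = 0, n = n))
  }
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Significance stars for p-values
#'
#' Star bands used when reporting module-trait correlations:
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}
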