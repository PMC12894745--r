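#' @keywords internal
"_PACKAGE"

# softplus, numerically stable for large |x|
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# population variance of each row (denominator n)
row_var_pop <- function(x) {
  mu <- rowMeans(x)
  rowMeans((x - mu)^2)
}

# Moore-Penrose pseudoinverse via SVD
pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 1)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# run expr with a local RNG state seeded at `seed`; never touches the
# caller's .Random.seed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derive a bounded substream seed from a base seed and a stage offset
substream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647L)
}

#' Area under the precision-recall curve
#'
#' Computes AUPR for a vector of scores against binary labels, handling tied
#' scores as single operating points (precision/recall evaluated at the end of
#' each tie group, average-precision style).
#'
#' @param scores numeric vector, higher means more confident positive.
#' @param labels logical or 0/1 vector of the same length.
#' @return scalar AUPR in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  k <- seq_along(l)
  last <- k[!duplicated(grp, fromLast = TRUE)]
  rec <- tp[last] / n_pos
  prec <- tp[last] / last
  sum(diff(c(0, rec)) * prec)
}
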