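#' Filter low-information genes
#'
#' Retains genes with a count of at least `min_count` in at least
#' `min_samples` samples and non-constant values across samples; row order is
#' preserved. An empty result is allowed (with a warning), since downstream
#' stages report their own errors.
#'
#' @param counts gene x sample count matrix.
#' @param min_count minimum count (default 2).
#' @param min_samples minimum number of samples reaching `min_count`
#'   (default 2).
#' @return the filtered matrix, counts layer.
#' @export
filter_genes <- function(counts, min_count = 2, min_samples = 2) {
  enough <- rowSums(counts >= min_count) >= min_samples
  non_constant <- apply(counts, 1L, function(r) any(r != r[1L]))
  keep <- enough & non_constant
  if (!any(keep)) warning("no genes pass the expression filter")
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- rownames(counts)[keep]   # survives an empty result
  expression_matrix(out, "counts")
}

#' Median-of-ratios size factors
#'
#' The per-sample factor is the median, over genes with strictly positive
#' counts in every sample, of the ratio of the gene's count to its geometric
#' mean across samples.
#'
#' @param counts gene x sample count matrix.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts <= 0) == 0L
  if (!any(pos))
    stop("no gene has strictly positive counts in every sample; ",
         "size factors are undefined (no pseudo-reference fallback is applied)")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg - ref, 2L, function(col) exp(stats::median(col)))
  stats::setNames(sf, colnames(counts))
}

#' Divide counts by size factors
#'
#' @param counts gene x sample count matrix.
#' @param factors size factors from [size_factors()]; computed if missing.
#' @return normalised matrix (normalised layer).
#' @export
normalise_counts <- function(counts, factors = size_factors(counts)) {
  stopifnot(all(factors > 0), length(factors) == ncol(counts))
  out <- sweep(counts, 2L, factors, "/")
  expression_matrix(out, "normalised")
}

#' Per-gene Welch contrast signature
#'
#' For each gene, computes the Welch (unequal-variance) t-statistic comparing
#' group A against group B (positive t means higher in A), a two-sided p-value
#' from the t distribution with Welch-Satterthwaite degrees of freedom, and a
#' signed z-score `z = sign(t) * qnorm(1 - p/2)` capped at |z| <= 8. Genes
#' with zero within-group variance and a non-zero shift are assigned the
#' capped z directly.
#'
#' @param expr normalised gene x sample matrix.
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @param z_cap cap on |z| (default 8).
#' @return data.frame with columns gene, t, p, z.
#' @export
contrast_signature <- function(expr, group_a, group_b, z_cap = 8) {
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples")
  miss <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(miss)) stop("samples absent from matrix: ",
                         paste(miss, collapse = ", "))
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  diff <- ma - mb
  t_stat <- ifelse(se2 > 0, diff / sqrt(se2),
                   ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               NA_real_)
  p <- ifelse(is.finite(t_stat) & se2 > 0,
              2 * stats::pt(-abs(t_stat), df),
              ifelse(t_stat == 0, 1, 2 * stats::pnorm(-z_cap)))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  z <- sign(t_stat) * stats::qnorm(1 - p / 2)
  z <- pmin(pmax(z, -z_cap), z_cap)
  z[t_stat == 0] <- 0
  z[se2 == 0 & diff != 0] <- sign(diff[se2 == 0 & diff != 0]) * z_cap
  data.frame(gene = rownames(expr), t = unname(t_stat), p = unname(p),
             z = unname(z), stringsAsFactors = FALSE)
}

#' Centre and scale each gene across samples
#'
#' Each gene is centred and scaled to unit (sample) variance across all
#' samples; zero-variance genes become all-zero rows. The standardised values
#' serve as per-sample gene signatures for per-time-point activity scoring.
#'
#' @param expr normalised gene x sample matrix, >= 2 samples.
#' @return standardised-layer matrix.
#' @export
standardise_genes <- function(expr) {
  stopifnot(ncol(expr) >= 2)
  mu <- rowMeans(expr)
  s <- sqrt(rowSums((expr - mu)^2) / (ncol(expr) - 1))
  out <- (expr - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  expression_matrix(out, "standardised")
}
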