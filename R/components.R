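# symmetric FastICA with the logcosh contrast on a whitened matrix.
# z: n x k whitened observations; returns the k x k unmixing matrix W
# (rows are unit unmixing vectors in whitened space).
fastica_core <- function(z, k, max_iter = 500, tol = 1e-8) {
  n <- nrow(z)
  W <- matrix(stats::rnorm(k * k), k, k)
  sym_decor <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-300)), k) %*%
      t(s$vectors) %*% W
  }
  W <- sym_decor(W)
  for (it in seq_len(max_iter)) {
    S <- z %*% t(W)               # n x k source estimates
    G <- tanh(S)
    Gp <- 1 - G^2
    W_new <- t(G) %*% z / n - diag(colMeans(Gp), k) %*% W
    W_new <- sym_decor(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) return(list(W = W, converged = TRUE, iter = it))
  }
  list(W = W, converged = FALSE, iter = max_iter)
}

# one seeded ICA run on centred X (genes x samples): rows are observations
# (genes), columns variables (samples). Returns metagenes S (genes x k) and
# mixing A (k x samples) with X_c ~ S A.
ica_single <- function(xc, k, seed, max_iter, tol) {
  n <- nrow(xc)
  sv <- svd(xc, nu = k, nv = 0)
  if (sv$d[k] < 1e-12 * sv$d[1])
    stop("data rank below k; reduce the number of components")
  # whitened coordinates: n x k with identity covariance (up to 1/n scaling)
  z <- sv$u[, seq_len(k), drop = FALSE] * sqrt(n)
  res <- with_seed(seed, fastica_core(z, k, max_iter, tol))
  if (!res$converged)
    warning("FastICA did not reach tolerance in ", max_iter, " iterations")
  S <- z %*% t(res$W)                       # genes x k, unit variance
  A <- solve(crossprod(S), crossprod(S, xc))  # k x samples
  list(S = S, A = A)
}

#' Independent component analysis with restart-stability matching
#'
#' Decomposes a centred gene x sample matrix as `X ~ M %*% A` where the
#' columns of the metagene matrix M are statistically independent over genes
#' (FastICA, logcosh contrast, symmetric decorrelation) and A holds the
#' metasample scores. The run is repeated `n_restarts` times from different
#' seeded initialisations; components of each restart are greedily matched to
#' the first run by absolute correlation of loadings, and the mean matched
#' |correlation| per component is reported as its stability. Conventions:
#' columns of M have unit norm and their largest-|loading| entry is positive.
#'
#' @param x gene x sample numeric matrix; rows are centred internally.
#' @param k number of components (default 10).
#' @param n_restarts restarts for the stability estimate (default 5).
#' @param seed base seed.
#' @param max_iter,tol FastICA iteration controls.
#' @return list of class `ica_result`: `metagenes` (genes x k), `metasamples`
#'   (k x samples), `k`, `seed`, `stability` (length-k in \\[0, 1\\]),
#'   `center` (per-sample means removed).
#' @export
ica_decompose <- function(x, k = 10, n_restarts = 5, seed = 1L,
                          max_iter = 500, tol = 1e-8) {
  stopifnot(k >= 1, k <= min(dim(x)))
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  runs <- lapply(seq_len(n_restarts), function(r)
    ica_single(xc, k, substream(seed, 7000L + r), max_iter, tol))
  ref <- runs[[1L]]
  match_abs_cor <- function(S) {
    cm <- abs(stats::cor(ref$S, S))
    matched <- numeric(k)
    taken <- rep(FALSE, k)
    for (i in order(-apply(cm, 1L, max))) {
      j <- which.max(ifelse(taken, -Inf, cm[i, ]))
      matched[i] <- cm[i, j]
      taken[j] <- TRUE
    }
    matched
  }
  stability <- if (n_restarts > 1) {
    rowMeans(vapply(runs[-1L], function(r) match_abs_cor(r$S), numeric(k)))
  } else rep(NA_real_, k)
  M <- ref$S
  A <- ref$A
  nrm <- sqrt(colSums(M^2))
  M <- sweep(M, 2L, nrm, "/")
  A <- A * nrm
  flip <- vapply(seq_len(k), function(j) {
    sign(M[which.max(abs(M[, j])), j])
  }, numeric(1))
  M <- sweep(M, 2L, flip, "*")
  A <- A * flip
  colnames(M) <- rownames(A) <- sprintf("IC%d", seq_len(k))
  rownames(M) <- rownames(x)
  colnames(A) <- colnames(x)
  structure(list(metagenes = M, metasamples = A, k = k, seed = seed,
                 stability = stats::setNames(stability, colnames(M)),
                 center = ctr),
            class = "ica_result")
}

#' Proportion of variance explained by a component subset
#'
#' Projects the data onto the column space of the selected metagene columns
#' with the Moore-Penrose pseudoinverse, `Xhat = M (M^T M)^{-1} M^T X`, and
#' reports `PVE = sum_genes Var(Xhat) / sum_genes Var(X)` with population
#' (denominator n) variances per gene; the denominator convention cancels in
#' the ratio. A rank-deficient restricted M falls back to the SVD
#' pseudoinverse with a warning.
#'
#' @param x gene x sample matrix (centred or not; variances are central).
#' @param m metagene matrix, rows aligned to `x`.
#' @param components optional column indices/names of `m` to use (default
#'   all).
#' @return list with `pve` in \\[0, 1\\] and `xhat` (the reconstruction).
#' @export
pve <- function(x, m, components = NULL) {
  if (!is.null(components)) m <- m[, components, drop = FALSE]
  stopifnot(nrow(m) == nrow(x))
  mtm <- crossprod(m)
  proj <- tryCatch(solve(mtm, crossprod(m, x)),
                   error = function(e) {
                     warning("restricted metagene matrix is rank-deficient; ",
                             "using the SVD pseudoinverse")
                     pinv(mtm) %*% crossprod(m, x)
                   })
  xhat <- m %*% proj
  val <- sum(row_var_pop(xhat)) / sum(row_var_pop(x))
  list(pve = val, xhat = xhat)
}

#' Per-component and cumulative PVE report
#'
#' @param x gene x sample matrix.
#' @param ica an [ica_decompose()] result (PVE is computed on the same
#'   centred matrix the decomposition used).
#' @return data.frame (component, pve_single, pve_cumulative) plus the full
#'   set's PVE as attribute `pve_full`.
#' @export
pve_report <- function(x, ica) {
  xc <- sweep(x, 2L, ica$center)
  M <- ica$metagenes
  singles <- vapply(seq_len(ncol(M)), function(j) pve(xc, M, j)$pve,
                    numeric(1))
  ord <- order(-singles)
  cums <- vapply(seq_along(ord), function(i)
    pve(xc, M, ord[seq_len(i)])$pve, numeric(1))
  out <- data.frame(component = colnames(M)[ord], pve_single = singles[ord],
                    pve_cumulative = cums, stringsAsFactors = FALSE)
  attr(out, "pve_full") <- pve(xc, M)$pve
  out
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least `k = |query intersect set|`
#' members of a gene set in a query of size n drawn from a universe of size
#' N containing K set members: `p = P(X >= k)`, X hypergeometric.
#'
#' @param query character vector, must be a subset of `universe`.
#' @param set character vector (intersected with the universe).
#' @param universe character vector of all eligible items.
#' @return list with k, K, n, N, p.
#' @export
ora <- function(query, set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (length(setdiff(query, universe)))
    stop("query contains items outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  set <- intersect(unique(set), universe)
  k <- length(intersect(query, set))
  K <- length(set)
  n <- length(query)
  N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to `stats::p.adjust`).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Read gene sets in GMT format
#'
#' One set per line: id, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) unique(x[-(1:2)])),
                  vapply(parts, `[`, character(1), 1L))
}
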