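#' Regulon enrichment score (NES)
#'
#' The activity score of a TF against a per-gene signature z is the weighted,
#' mode-signed sum over its measured targets, normalised by the Euclidean norm
#' of the weights: `NES = sum(w * m * z) / sqrt(sum(w^2))`. It is linear in
#' the signature and flips sign when all regulon modes flip.
#'
#' @param signature named numeric vector of per-gene z-scores (names are gene
#'   ids).
#' @param reg_tf regulon rows of one TF (columns target, mode, weight).
#' @param min_targets minimum number of measured targets (default 5); TFs
#'   below it are skipped (NA returned).
#' @return list with `nes` and `n_targets_used` (`nes` is NA when skipped).
#' @export
nes_score <- function(signature, reg_tf, min_targets = 5) {
  idx <- match(reg_tf$target, names(signature))
  ok <- !is.na(idx)
  n_used <- sum(ok)
  if (n_used < min_targets)
    return(list(nes = NA_real_, n_targets_used = n_used))
  w <- reg_tf$weight[ok]
  m <- reg_tf$mode[ok]
  z <- signature[idx[ok]]
  list(nes = sum(w * m * z) / sqrt(sum(w^2)), n_targets_used = n_used)
}

#' Gene-permutation p-value for an enrichment score
#'
#' The null distribution draws, for each of `n_perm` permutations, a random
#' set of gene labels of the same size as the TF's measured target set and
#' recomputes the NES, i.e. gene labels of the signature are shuffled while
#' regulon structure (weights, modes) is fixed. Two-sided with add-one
#' correction: `p = (1 + #{|null| >= |observed|}) / (n_perm + 1)`.
#'
#' @inheritParams nes_score
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutation draws.
#' @return list with `nes`, `p`, `n_targets_used`.
#' @export
permutation_p <- function(signature, reg_tf, min_targets = 5,
                          n_perm = 1000, seed = 1L) {
  obs <- nes_score(signature, reg_tf, min_targets)
  if (is.na(obs$nes)) return(c(obs, list(p = NA_real_)))
  idx <- match(reg_tf$target, names(signature))
  ok <- !is.na(idx)
  w <- reg_tf$weight[ok]
  m <- reg_tf$mode[ok]
  denom <- sqrt(sum(w^2))
  nt <- sum(ok)
  g <- length(signature)
  null_nes <- with_seed(seed, {
    draws <- matrix(NA_real_, nt, n_perm)
    for (j in seq_len(n_perm))
      draws[, j] <- signature[sample.int(g, nt)]
    colSums(draws * (w * m)) / denom
  })
  p <- (1 + sum(abs(null_nes) >= abs(obs$nes))) / (n_perm + 1)
  list(nes = obs$nes, p = p, n_targets_used = obs$n_targets_used)
}

#' Per-sample TF activity matrix
#'
#' Scores every TF against every sample, using the sample's standardised
#' per-gene values as its signature. Deterministic (no permutation testing).
#' TFs with fewer than `min_targets` measured targets are dropped and recorded
#' in the `skipped` attribute.
#'
#' @param std_expr standardised gene x sample matrix
#'   (see [standardise_genes()]).
#' @param reg a [regulon()] table.
#' @param min_targets minimum measured targets per TF (default 5).
#' @return TF x sample matrix of NES values with attribute `skipped`.
#' @export
activity_matrix <- function(std_expr, reg, min_targets = 5) {
  tfs <- unique(reg$tf)
  by_tf <- split(reg, reg$tf)[tfs]
  rows <- lapply(by_tf, function(rt) {
    idx <- match(rt$target, rownames(std_expr))
    ok <- !is.na(idx)
    if (sum(ok) < min_targets) return(NULL)
    w <- rt$weight[ok] * rt$mode[ok]
    colSums(std_expr[idx[ok], , drop = FALSE] * w) /
      sqrt(sum(rt$weight[ok]^2))
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no TF has enough measured targets")
  act <- do.call(rbind, rows[keep])
  rownames(act) <- tfs[keep]
  attr(act, "skipped") <- tfs[!keep]
  act
}

#' Differential TF activity between successive time points
#'
#' For one patient and condition, builds for each pair of consecutive design
#' days the Welch contrast signature (later vs earlier day), scores each TF
#' (NES + gene-permutation p), and zeroes the stored score whenever
#' `p > alpha`. Missing time points are skipped with a warning.
#'
#' @param norm_expr normalised gene x sample matrix.
#' @param design a [sample_design()].
#' @param reg a [regulon()].
#' @param patient,condition which series to contrast.
#' @param alpha zeroing threshold on the permutation p (default 0.05).
#' @param n_perm permutations per test (default 1000).
#' @param min_targets minimum measured targets per TF.
#' @param seed base seed; each (interval, TF) test uses a derived substream.
#' @return data.frame with columns tf, patient, condition, day_a, day_b,
#'   nes_raw, score (zeroed), p.
#' @export
differential_activity <- function(norm_expr, design, reg, patient, condition,
                                  alpha = 0.05, n_perm = 1000,
                                  min_targets = 5, seed = 1L) {
  sel <- design[design$patient == patient & design$condition == condition, ]
  days <- sort(unique(sel$day))
  if (length(days) < 2) stop("need at least two time points")
  tfs <- unique(reg$tf)
  by_tf <- split(reg, reg$tf)[tfs]
  out <- list()
  for (k in seq_len(length(days) - 1L)) {
    d_a <- days[k]; d_b <- days[k + 1L]
    earlier <- sel$sample_id[sel$day == d_a]
    later <- sel$sample_id[sel$day == d_b]
    if (length(earlier) < 2 || length(later) < 2) {
      warning(sprintf("interval (%d,%d) of %s/%s skipped: fewer than 2 replicates",
                      d_a, d_b, patient, condition))
      next
    }
    sig <- contrast_signature(norm_expr, later, earlier)
    z <- stats::setNames(sig$z, sig$gene)
    for (i in seq_along(by_tf)) {
      res <- permutation_p(z, by_tf[[i]], min_targets, n_perm,
                           seed = substream(seed, k * 1000L + i))
      if (is.na(res$nes)) next
      out[[length(out) + 1L]] <- data.frame(
        tf = tfs[i], patient = patient, condition = condition,
        day_a = d_a, day_b = d_b, nes_raw = res$nes,
        score = if (res$p > alpha) 0 else res$nes, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(tf = character(), patient = character(),
                      condition = character(), day_a = integer(),
                      day_b = integer(), nes_raw = numeric(),
                      score = numeric(), p = numeric()))
  do.call(rbind, out)
}

#' Differential activity over every patient and condition
#'
#' @inheritParams differential_activity
#' @return row-bound [differential_activity()] tables for all
#'   (patient, condition) series in the design.
#' @export
differential_activity_all <- function(norm_expr, design, reg, alpha = 0.05,
                                      n_perm = 1000, min_targets = 5,
                                      seed = 1L) {
  combos <- unique(design[, c("patient", "condition")])
  tabs <- mapply(function(p, cond, off) {
    differential_activity(norm_expr, design, reg, p, cond, alpha, n_perm,
                          min_targets, seed = substream(seed, off))
  }, combos$patient, combos$condition, seq_len(nrow(combos)) * 101L,
  SIMPLIFY = FALSE)
  do.call(rbind, c(tabs, make.row.names = FALSE))
}

#' Select differentially activated (DA) TFs
#'
#' A TF is selected when its differential activity is significant
#' (`p < alpha`) in at least one interval of one patient/condition series.
#' Tags record where each TF fired.
#'
#' @param da_table output of [differential_activity_all()].
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per selected TF: tf, conditions, patients,
#'   intervals (comma-joined tags), n_hits; the significant rows themselves
#'   are attached as attribute `hits`.
#' @export
select_da_tfs <- function(da_table, alpha = 0.05) {
  hits <- da_table[da_table$p < alpha, , drop = FALSE]
  if (nrow(hits) == 0L)
    stop("no TF is differentially activated at alpha = ", alpha,
         "; downstream network undefined")
  hits$interval <- sprintf("d%d-d%d", hits$day_a, hits$day_b)
  agg <- function(x) paste(sort(unique(x)), collapse = ",")
  out <- do.call(rbind, lapply(split(hits, hits$tf), function(h) {
    data.frame(tf = h$tf[1], conditions = agg(h$condition),
               patients = agg(h$patient), intervals = agg(h$interval),
               n_hits = nrow(h), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$tf), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hits") <- hits
  out
}

#' Over-representation of gene sets among DA TFs and their targets
#'
#' Builds the query as the union of the selected TFs and their regulon
#' targets, then runs the hypergeometric upper-tail test of [ora()] per gene
#' set, BH-adjusted.
#'
#' @param da_set a [select_da_tfs()] table (or character vector of TFs).
#' @param reg a [regulon()].
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all eligible genes.
#' @return data.frame of [ora()] rows with `p_adj`.
#' @export
ora_tf_targets <- function(da_set, reg, gene_sets, universe) {
  tfs <- if (is.data.frame(da_set)) da_set$tf else as.character(da_set)
  query <- union(tfs, reg$target[reg$tf %in% tfs])
  query <- intersect(query, universe)
  rows <- lapply(names(gene_sets), function(id) {
    r <- ora(query, gene_sets[[id]], universe)
    cbind(data.frame(set = id, stringsAsFactors = FALSE), as.data.frame(r))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}
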