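#' Estimate TF activity decay rates
#'
#' Activity scores can be negative, so each TF's pooled series is shifted so
#' its minimum is 0 and offset by epsilon = 1 before taking the log dynamic
#' range: `alpha_i = log((max + eps) / eps) / (t_last - t_first)`. The pooled
#' rate used in fitting is the median over TFs.
#'
#' @param activity TF x sample matrix.
#' @param design matching [sample_design()] (supplies first/last day).
#' @param eps offset (default 1).
#' @return list with `per_tf` (named vector) and `pooled` (median).
#' @export
estimate_decay <- function(activity, design, eps = 1) {
  days <- sort(unique(design$day))
  if (length(days) < 2) stop("need at least two time points")
  span <- days[length(days)] - days[1]
  per_tf <- apply(activity, 1L, function(x) {
    rng <- max(x) - min(x)
    log((rng + eps) / eps) / span
  })
  list(per_tf = per_tf, pooled = stats::median(per_tf))
}

# training pairs for the semi-parametric ODE regression:
# one row per (series, consecutive-day pair); response for target i is
# (x_i(t+dt) - x_i(t))/dt + alpha * x_i(t), predictors all activities at t
dyn_training_set <- function(activity, design, condition, alpha) {
  sel <- design[design$condition == condition, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no samples in condition ", condition)
  series <- split(sel, list(sel$patient, sel$replicate), drop = TRUE)
  X <- list(); Y <- list()
  for (s in series) {
    s <- s[order(s$day), , drop = FALSE]
    if (nrow(s) < 2) stop("a series has fewer than 2 time points")
    a <- activity[, s$sample_id, drop = FALSE]
    for (k in seq_len(nrow(s) - 1L)) {
      dt <- s$day[k + 1L] - s$day[k]
      X[[length(X) + 1L]] <- a[, k]
      Y[[length(Y) + 1L]] <- (a[, k + 1L] - a[, k]) / dt + alpha * a[, k]
    }
  }
  list(x = do.call(rbind, X), y = do.call(rbind, Y))
}

#' Tree-ensemble semi-parametric ODE network inference (single run)
#'
#' dynGENIE3-style: for each target TF i, regresses
#' `(x_i(t_{k+1}) - x_i(t_k))/dt + alpha * x_i(t_k)` on all TF activities at
#' `t_k` with a random forest (or extra-trees) of `n_trees`, feature
#' subsample `floor(sqrt(p))`. The normalised impurity importance of
#' regulator j for target i is the edge weight w(j -> i); the target's own
#' importance is discarded before normalisation (decay already models
#' self-dependence). Targets with zero response variance receive no incoming
#' edges.
#'
#' @param activity TF x sample activity matrix.
#' @param design matching [sample_design()].
#' @param condition which condition's series to fit.
#' @param alpha pooled decay rate (see [estimate_decay()]).
#' @param n_trees trees per forest (default 1000).
#' @param method `"rf"` (random forest) or `"et"` (extra-trees).
#' @param seed RNG seed for the ensembles.
#' @return data.frame (regulator, target, weight) with per-target weights
#'   summing to 1 (when the response varies).
#' @export
fit_dyn_network <- function(activity, design, condition, alpha,
                            n_trees = 1000, method = c("rf", "et"),
                            seed = 1L) {
  method <- match.arg(method)
  tr <- dyn_training_set(activity, design, condition, alpha)
  tfs <- rownames(activity)
  p <- length(tfs)
  mtry <- max(1L, floor(sqrt(p - 1L)))
  edges <- list()
  for (i in seq_len(p)) {
    y <- tr$y[, i]
    if (stats::var(y) == 0) next
    dat <- as.data.frame(tr$x)
    names(dat) <- tfs
    dat$.y <- y
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = dat,
      num.trees = n_trees, mtry = mtry, importance = "impurity",
      min.node.size = 2,
      splitrule = if (method == "et") "extratrees" else "variance",
      replace = method != "et",
      sample.fraction = 1,
      num.random.splits = 1L,
      seed = substream(seed, i), num.threads = 1L)
    imp <- fit$variable.importance[tfs]
    imp[tfs[i]] <- 0            # discard self-importance
    imp[imp < 0 | is.na(imp)] <- 0
    tot <- sum(imp)
    if (tot == 0) next
    w <- imp / tot
    keep <- w > 0 & tfs != tfs[i]
    edges[[length(edges) + 1L]] <- data.frame(
      regulator = tfs[keep], target = tfs[i], weight = unname(w[keep]),
      stringsAsFactors = FALSE)
  }
  if (!length(edges))
    return(data.frame(regulator = character(), target = character(),
                      weight = numeric()))
  do.call(rbind, c(edges, make.row.names = FALSE))
}

#' Intersect repeated inference runs
#'
#' An edge survives iff its weight is at least `w_min` in every run; the
#' reported weight is the mean across runs. With a single run this reduces to
#' a plain threshold filter.
#'
#' @param runs list of [fit_dyn_network()] edge tables from distinct seeds.
#' @param w_min weight threshold (default 0.01).
#' @return edge data.frame (regulator, target, weight).
#' @export
stability_intersect <- function(runs, w_min = 0.01) {
  if (!length(runs)) stop("empty run sequence")
  n_runs <- length(runs)
  key <- function(e) paste(e$regulator, e$target, sep = "\r")
  all_keys <- unique(unlist(lapply(runs, key)))
  wmat <- matrix(0, length(all_keys), n_runs,
                 dimnames = list(all_keys, NULL))
  for (j in seq_len(n_runs)) {
    e <- runs[[j]]
    wmat[key(e), j] <- e$weight
  }
  keep <- rowSums(wmat >= w_min) == n_runs
  if (!any(keep))
    return(data.frame(regulator = character(), target = character(),
                      weight = numeric()))
  parts <- do.call(rbind, strsplit(all_keys[keep], "\r", fixed = TRUE))
  out <- data.frame(regulator = parts[, 1], target = parts[, 2],
                    weight = rowMeans(wmat[keep, , drop = FALSE]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$weight), , drop = FALSE]
}

#' Merge condition-specific directed networks
#'
#' Edge union over the two conditions; the merged weight is the maximum of
#' the per-condition weights (an edge exists if it exists in either
#' condition), and per-edge tags record where it was found.
#'
#' @param net_auto,net_mono edge tables (regulator, target, weight).
#' @return edge data.frame with a `conditions` tag column.
#' @export
merge_conditions <- function(net_auto, net_mono) {
  tag <- function(e, cond) {
    if (nrow(e)) cbind(e, cond = cond, stringsAsFactors = FALSE)
    else cbind(e, cond = character(0))
  }
  both <- rbind(tag(net_auto, "autologous"), tag(net_mono, "monoculture"))
  if (nrow(both) == 0L)
    return(data.frame(regulator = character(), target = character(),
                      weight = numeric(), conditions = character()))
  k <- paste(both$regulator, both$target, sep = "\r")
  out <- do.call(rbind, lapply(split(both, k), function(g) {
    data.frame(regulator = g$regulator[1], target = g$target[1],
               weight = max(g$weight),
               conditions = paste(sort(unique(g$cond)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(-out$weight), , drop = FALSE]
}

#' Differential-activity Pearson correlation network
#'
#' Each TF selected in the condition gets a vector of its stored differential
#' activity scores (zeros included) over all (patient, interval) cells in a
#' fixed order; Pearson correlation over all TF pairs forms an undirected
#' signed edge whenever `|r| >= cor_min`. Pairs where either vector has zero
#' variance are skipped.
#'
#' @param da_table a [differential_activity_all()] table.
#' @param condition which condition's scores to correlate.
#' @param cor_min absolute-correlation threshold (default 0.5).
#' @param tfs optional restriction of the TF universe (defaults to TFs with a
#'   significant interval in this condition).
#' @param alpha significance threshold used for the default TF selection.
#' @return data.frame (tf_a, tf_b, cor, sign), tf_a < tf_b.
#' @export
diff_corr_network <- function(da_table, condition, cor_min = 0.5,
                              tfs = NULL, alpha = 0.05) {
  sub <- da_table[da_table$condition == condition, , drop = FALSE]
  if (is.null(tfs))
    tfs <- sort(unique(sub$tf[sub$p < alpha]))
  sub <- sub[sub$tf %in% tfs, , drop = FALSE]
  if (length(tfs) < 2 || nrow(sub) == 0L)
    return(data.frame(tf_a = character(), tf_b = character(),
                      cor = numeric(), sign = numeric()))
  cell <- paste(sub$patient, sub$day_a, sub$day_b, sep = "\r")
  cells <- sort(unique(cell))
  if (length(cells) < 2) stop("fewer than 2 (patient, interval) cells")
  m <- matrix(0, length(cells), length(tfs), dimnames = list(cells, tfs))
  m[cbind(match(cell, cells), match(sub$tf, tfs))] <- sub$score
  sds <- apply(m, 2L, stats::sd)
  usable <- sds > 0
  if (sum(usable) < 2)
    return(data.frame(tf_a = character(), tf_b = character(),
                      cor = numeric(), sign = numeric()))
  cm <- stats::cor(m[, usable, drop = FALSE])
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  keep <- abs(r) >= cor_min
  data.frame(tf_a = rownames(cm)[ut[keep, 1]],
             tf_b = colnames(cm)[ut[keep, 2]],
             cor = r[keep], sign = sign(r[keep]),
             stringsAsFactors = FALSE)
}

#' Merge condition-specific correlation networks
#'
#' Pair union; when the two conditions disagree on the sign of a pair, the
#' entry with the larger |r| is kept.
#'
#' @param corr_auto,corr_mono [diff_corr_network()] tables.
#' @return merged pair table with a `conditions` tag column.
#' @export
merge_corr_conditions <- function(corr_auto, corr_mono) {
  tag <- function(e, cond) {
    if (nrow(e)) cbind(e, cond = cond, stringsAsFactors = FALSE)
    else cbind(e, cond = character(0))
  }
  both <- rbind(tag(corr_auto, "autologous"), tag(corr_mono, "monoculture"))
  if (nrow(both) == 0L)
    return(data.frame(tf_a = character(), tf_b = character(),
                      cor = numeric(), sign = numeric(),
                      conditions = character()))
  pk <- apply(cbind(pmin(both$tf_a, both$tf_b),
                    pmax(both$tf_a, both$tf_b)), 1L, paste, collapse = "\r")
  out <- do.call(rbind, lapply(split(both, pk), function(g) {
    best <- which.max(abs(g$cor))
    data.frame(tf_a = min(g$tf_a[1], g$tf_b[1]),
               tf_b = max(g$tf_a[1], g$tf_b[1]),
               cor = g$cor[best], sign = g$sign[best],
               conditions = paste(sort(unique(g$cond)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Signed consensus network
#'
#' Keeps a directed edge i -> j of the tree-ensemble network iff the
#' unordered pair {i, j} is an edge of the correlation network; the sign and
#' correlation are copied from the pair. If both orientations survive, both
#' are retained as distinct edges.
#'
#' @param directed_net merged directed edge table
#'   (regulator, target, weight, ...).
#' @param corr_net merged pair table (tf_a, tf_b, cor, sign, ...).
#' @return data.frame (regulator, target, weight, cor, sign, conditions).
#' @export
consensus_network <- function(directed_net, corr_net) {
  if (nrow(directed_net) == 0L || nrow(corr_net) == 0L)
    return(data.frame(regulator = character(), target = character(),
                      weight = numeric(), cor = numeric(), sign = numeric(),
                      conditions = character()))
  pk_dir <- paste(pmin(directed_net$regulator, directed_net$target),
                  pmax(directed_net$regulator, directed_net$target),
                  sep = "\r")
  pk_cor <- paste(corr_net$tf_a, corr_net$tf_b, sep = "\r")
  hit <- match(pk_dir, pk_cor)
  keep <- !is.na(hit)
  out <- data.frame(
    regulator = directed_net$regulator[keep],
    target = directed_net$target[keep],
    weight = directed_net$weight[keep],
    cor = corr_net$cor[hit[keep]],
    sign = corr_net$sign[hit[keep]],
    conditions = if (!is.null(directed_net$conditions))
      directed_net$conditions[keep] else NA_character_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Evaluate network recovery against a simulated ground truth
#'
#' Scores every ordered non-self TF pair with the consensus weight (0 when
#' absent), computes the area under the precision-recall curve against the
#' ground-truth edge set, the density baseline (prevalence of true edges),
#' and the fraction of true-positive consensus edges whose sign matches the
#' ground-truth edge sign.
#'
#' @param consensus a [consensus_network()] table.
#' @param truth_net a [sample_ground_truth()] network.
#' @return list with `aupr`, `baseline`, `fold` (aupr/baseline),
#'   `sign_accuracy`, `n_true_positive`, `n_predicted`.
#' @export
evaluate_recovery <- function(consensus, truth_net) {
  tfs <- truth_net$tfs
  pairs <- expand.grid(regulator = tfs, target = tfs,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, , drop = FALSE]
  kp <- paste(pairs$regulator, pairs$target, sep = "\r")
  kt <- paste(truth_net$edges$regulator, truth_net$edges$target, sep = "\r")
  labels <- kp %in% kt
  scores <- numeric(length(kp))
  if (nrow(consensus)) {
    kc <- paste(consensus$regulator, consensus$target, sep = "\r")
    idx <- match(kc, kp)
    scores[idx[!is.na(idx)]] <- consensus$weight[!is.na(idx)]
  }
  au <- aupr(scores, labels)
  base <- mean(labels)
  tp_sign <- NA_real_
  n_tp <- 0L
  if (nrow(consensus)) {
    kc <- paste(consensus$regulator, consensus$target, sep = "\r")
    hit <- match(kc, kt)
    tp <- !is.na(hit)
    n_tp <- sum(tp)
    if (n_tp > 0)
      tp_sign <- mean(consensus$sign[tp] == truth_net$edges$sign[hit[tp]])
  }
  list(aupr = au, baseline = base, fold = au / base,
       sign_accuracy = tp_sign, n_true_positive = n_tp,
       n_predicted = nrow(consensus))
}
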