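# undirected simple igraph from an edge table with regulator/target or
# tf_a/tf_b (or source/target) columns
as_undirected_graph <- function(net, nodes = NULL) {
  cols <- intersect(c("regulator", "source", "tf_a"), names(net))[1]
  colt <- intersect(c("target", "tf_b"), names(net))[1]
  e <- data.frame(from = net[[cols]], to = net[[colt]],
                  stringsAsFactors = FALSE)
  verts <- unique(c(e$from, e$to, nodes))
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(name = verts))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

# neighbour name lists of an igraph, indexed by vertex name
neighbour_names <- function(g) {
  nodes <- igraph::V(g)$name
  stats::setNames(
    lapply(igraph::as_adj_list(g), function(vs) nodes[as.integer(vs)]),
    nodes)
}

#' Annotate consensus-network nodes with DA features
#'
#' Collapses the multi-membership tags of [select_da_tfs()] to single nominal
#' labels per feature: condition becomes `both` when a TF fired in both
#' cultures, patient becomes `shared`, and the time interval becomes
#' `multiple`, so each node carries exactly one label per feature.
#'
#' @param da_set a [select_da_tfs()] table.
#' @return data.frame with columns name, condition_tag, patient_tag,
#'   time_tag.
#' @export
annotate_nodes <- function(da_set) {
  collapse <- function(x, multi) ifelse(grepl(",", x, fixed = TRUE), multi, x)
  data.frame(name = da_set$tf,
             condition_tag = collapse(da_set$conditions, "both"),
             patient_tag = collapse(da_set$patients, "shared"),
             time_tag = collapse(da_set$intervals, "multiple"),
             stringsAsFactors = FALSE)
}

#' Betweenness centrality of the consensus network
#'
#' Exact shortest-path betweenness (unnormalised pair counts) on the
#' undirected, unweighted simple projection of the network.
#'
#' @param net edge table (regulator/target or source/target columns).
#' @param annotations optional [annotate_nodes()] table; when given, per
#'   feature-class mean/median summaries are attached as attribute
#'   `summaries`.
#' @return data.frame (name, betweenness) sorted decreasing.
#' @export
betweenness_table <- function(net, annotations = NULL) {
  g <- as_undirected_graph(net)
  if (igraph::vcount(g) == 0L) stop("empty graph")
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  out <- data.frame(name = names(b), betweenness = unname(b),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$betweenness, out$name), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(annotations)) {
    ann <- merge(out, annotations, by = "name")
    summaries <- lapply(c("condition_tag", "patient_tag", "time_tag"),
                        function(f) {
      agg <- split(ann$betweenness, ann[[f]])
      data.frame(feature = f, class = names(agg),
                 mean = vapply(agg, mean, numeric(1)),
                 median = vapply(agg, stats::median, numeric(1)),
                 row.names = NULL, stringsAsFactors = FALSE)
    })
    attr(out, "summaries") <- do.call(rbind, summaries)
  }
  out
}

#' Nominal attribute assortativity
#'
#' Newman's category mixing coefficient on the undirected edge set:
#' `r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)`, where e is the
#' mixing matrix (each undirected edge counted in both orientations) and
#' a, b its marginals. r = 1 for perfectly assortative graphs (e.g. disjoint
#' same-label cliques), negative when labels preferentially mix.
#'
#' @param net edge table.
#' @param labels named character vector mapping every node to its label.
#' @return scalar r, or NA (with a message) when only one label class is
#'   present among edge endpoints (denominator 0).
#' @export
assortativity_nominal <- function(net, labels) {
  g <- as_undirected_graph(net, nodes = names(labels))
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L) stop("graph has no edges")
  miss <- setdiff(unique(c(el)), names(labels))
  if (length(miss)) stop("unlabelled nodes: ", paste(miss, collapse = ", "))
  r <- mixing_r(labels[el[, 1]], labels[el[, 2]])
  if (is.na(r))
    message("single label class among connected nodes; assortativity undefined")
  r
}

# Newman mixing-matrix coefficient from per-edge endpoint labels
# (each undirected edge contributes both orientations)
mixing_r <- function(la, lb) {
  cats <- sort(unique(c(la, lb)))
  if (length(cats) < 2) return(NA_real_)
  e <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (k in seq_along(la)) {
    e[la[k], lb[k]] <- e[la[k], lb[k]] + 1
    e[lb[k], la[k]] <- e[lb[k], la[k]] + 1
  }
  e <- e / sum(e)
  ai <- rowSums(e)
  bi <- colSums(e)
  (sum(diag(e)) - sum(ai * bi)) / (1 - sum(ai * bi))
}

#' Assortativity z-test against a label-shuffle null
#'
#' Holds the topology fixed and permutes the node labels `n_shuffles` times;
#' `z = (r_obs - mean(null)) / sd(null)`.
#'
#' @inheritParams assortativity_nominal
#' @param n_shuffles number of label permutations (default 100).
#' @param seed RNG seed.
#' @return list with r, null_mean, null_sd, z (NA when sd is 0), n_shuffles.
#' @export
assortativity_ztest <- function(net, labels, n_shuffles = 100, seed = 1L) {
  g <- as_undirected_graph(net, nodes = names(labels))
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L) stop("graph has no edges")
  miss <- setdiff(unique(c(el)), names(labels))
  if (length(miss)) stop("unlabelled nodes: ", paste(miss, collapse = ", "))
  ia <- match(el[, 1], names(labels))
  ib <- match(el[, 2], names(labels))
  r_obs <- mixing_r(labels[ia], labels[ib])
  null_r <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      perm <- sample(unname(labels))
      mixing_r(perm[ia], perm[ib])
    }, numeric(1))
  })
  mu <- mean(null_r, na.rm = TRUE)
  sdv <- stats::sd(null_r, na.rm = TRUE)
  z <- if (is.na(sdv) || sdv == 0) NA_real_ else (r_obs - mu) / sdv
  list(r = r_obs, null_mean = mu, null_sd = sdv, z = z,
       n_shuffles = n_shuffles)
}

#' Edge clustering coefficient
#'
#' `ECC(u, v) = (#triangles on (u, v) + 1) / min(deg(u) - 1, deg(v) - 1)`;
#' edges with a degree-1 endpoint get ECC 0. High ECC marks intra-module
#' edges.
#'
#' @param net edge table.
#' @return data.frame (from, to, ecc) on the undirected simple projection.
#' @export
edge_clustering_coefficient <- function(net) {
  g <- as_undirected_graph(net)
  el <- igraph::as_edgelist(g)
  deg <- igraph::degree(g)
  adj <- neighbour_names(g)
  ecc <- vapply(seq_len(nrow(el)), function(k) {
    u <- el[k, 1]; v <- el[k, 2]
    if (deg[u] <= 1 || deg[v] <= 1) return(0)
    tri <- length(intersect(adj[[u]], adj[[v]]))
    (tri + 1) / min(deg[u] - 1, deg[v] - 1)
  }, numeric(1))
  data.frame(from = el[, 1], to = el[, 2], ecc = ecc,
             stringsAsFactors = FALSE)
}

#' ECC-ordered agglomerative community detection
#'
#' Fast agglomeration on edge clustering coefficients: every node starts as a
#' singleton cluster; edges are visited in decreasing ECC (ties broken
#' lexicographically by endpoint names, for determinism) and the two endpoint
#' clusters are merged unless both already qualify as modules. A cluster is a
#' module when its total internal degree exceeds its external degree
#' (2 x internal edges > boundary edges), so clusters stop absorbing
#' neighbours once they are well separated. Clusters of size >= `min_size`
#' are reported as modules; remaining nodes are listed as unassigned.
#'
#' @param net edge table.
#' @param min_size minimum module size to report (default 5).
#' @return list with `modules` (list of sorted node-name vectors, largest
#'   first), `unassigned` (node names) and `membership` (named integer, 0 =
#'   unassigned).
#' @export
ecc_communities <- function(net, min_size = 5) {
  g <- as_undirected_graph(net)
  if (igraph::vcount(g) == 0L) stop("empty graph")
  nodes <- igraph::V(g)$name
  ecc <- edge_clustering_coefficient(net)
  a <- pmin(ecc$from, ecc$to); b <- pmax(ecc$from, ecc$to)
  ord <- order(-ecc$ecc, a, b)
  el <- cbind(a, b)[ord, , drop = FALSE]
  adj <- neighbour_names(g)
  cluster <- stats::setNames(seq_along(nodes), nodes)
  is_module <- function(node) {
    memb_set <- nodes[cluster == cluster[node]]
    internal2 <- 0; external <- 0
    for (u in memb_set) {
      nb <- adj[[u]]
      inside <- sum(nb %in% memb_set)
      internal2 <- internal2 + inside
      external <- external + (length(nb) - inside)
    }
    internal2 > external
  }
  for (k in seq_len(nrow(el))) {
    u <- el[k, 1]; v <- el[k, 2]
    cu <- cluster[u]; cv <- cluster[v]
    if (cu == cv) next
    if (is_module(u) && is_module(v)) next
    cluster[cluster == cv] <- cu
  }
  sizes <- table(cluster)
  big <- names(sizes)[sizes >= min_size]
  modules <- lapply(big, function(cid) sort(nodes[cluster == as.integer(cid)]))
  modules <- modules[order(-vapply(modules, length, integer(1)),
                           vapply(modules, `[`, character(1), 1))]
  assigned <- unlist(modules)
  membership <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_along(modules)) membership[modules[[i]]] <- i
  list(modules = modules,
       unassigned = sort(setdiff(nodes, assigned)),
       membership = membership)
}

#' Cross-tabulate module membership against node features
#'
#' @param partition an [ecc_communities()] result.
#' @param annotations an [annotate_nodes()] table.
#' @return data.frame with one row per (module, feature, class) count plus
#'   the per-module majority label of each feature.
#' @export
module_feature_table <- function(partition, annotations) {
  if (!length(partition$modules))
    return(data.frame(module = integer(), feature = character(),
                      class = character(), count = integer(),
                      majority = logical()))
  rows <- list()
  for (i in seq_along(partition$modules)) {
    members <- partition$modules[[i]]
    ann <- annotations[match(members, annotations$name), , drop = FALSE]
    for (f in c("condition_tag", "patient_tag", "time_tag")) {
      tab <- table(ann[[f]])
      rows[[length(rows) + 1L]] <- data.frame(
        module = i, feature = f, class = names(tab),
        count = as.integer(tab),
        majority = as.integer(tab) == max(tab),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Modularity-based communities (cross-check)
#'
#' Standard greedy modularity optimisation (igraph's fast-greedy) on the same
#' undirected simple projection, provided as an independent cross-check for
#' [ecc_communities()].
#'
#' @param net edge table.
#' @param min_size minimum module size to report.
#' @return list in the same shape as [ecc_communities()].
#' @export
modularity_communities <- function(net, min_size = 5) {
  g <- as_undirected_graph(net)
  cl <- igraph::cluster_fast_greedy(g)
  memb <- igraph::membership(cl)
  nodes <- igraph::V(g)$name
  sizes <- table(memb)
  big <- names(sizes)[sizes >= min_size]
  modules <- lapply(big, function(cid) sort(nodes[memb == as.integer(cid)]))
  modules <- modules[order(-vapply(modules, length, integer(1)))]
  assigned <- unlist(modules)
  membership <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_along(modules)) membership[modules[[i]]] <- i
  list(modules = modules, unassigned = sort(setdiff(nodes, assigned)),
       membership = membership)
}
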