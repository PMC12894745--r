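# small deterministic fixtures shared across test files

toy_counts <- function() {
  m <- matrix(c(2, 4,
                8, 16), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expression_matrix(m, "counts")
}

toy_design <- function(n_days = 2, n_reps = 2, patients = "p1",
                       conditions = c("autologous", "monoculture")) {
  days <- c(1L, 4L, 8L, 11L, 14L)[seq_len(n_days)]
  grid <- expand.grid(patient = patients, condition = conditions,
                      day = days, replicate = seq_len(n_reps),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_r%d_d%02d", grid$patient,
                            substr(grid$condition, 1, 4), grid$replicate,
                            grid$day)
  sample_design(grid$sample_id, grid$patient, grid$condition, grid$day,
                grid$replicate)
}

# tiny simulation config that keeps tests fast
tiny_sim <- function(...) {
  args <- list(n_tfs = 6, edge_density = 0.2, targets_per_tf = 6,
               n_background_genes = 40)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# random undirected edge table on n nodes (gnp), at least one edge
random_edge_table <- function(n, p = 0.2) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  el <- igraph::as_edgelist(g)
  data.frame(source = el[, 1], target = el[, 2], stringsAsFactors = FALSE)
}

# k-clique edge table with a node-name prefix
clique_edges <- function(k, prefix) {
  nodes <- paste0(prefix, seq_len(k))
  idx <- t(utils::combn(k, 2))
  data.frame(source = nodes[idx[, 1]], target = nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}
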