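#' Configuration for the synthetic benchmark generator
#'
#' Defaults emulate the study design the pipeline targets: 3 patients, two
#' culture conditions (autologous PBMC culture vs CLL monoculture), 2
#' technical replicates, sampling days 1, 4, 8, 11 and 14. TF activities
#' follow a signed, saturating ODE with first-order decay; regulon target
#' genes emit negative-binomial counts driven by the activity of their TF.
#'
#' @param n_tfs number of transcription factors in the ground-truth network.
#' @param edge_density probability that an ordered non-self TF pair carries a
#'   regulatory edge.
#' @param frac_negative fraction of edges that are inhibitory (sign -1).
#' @param frac_condition_specific fraction of edges active in only one
#'   condition.
#' @param n_patients,n_replicates,days the sampling design.
#' @param decay_range range (per day) of the uniform draw for TF decay rates.
#' @param strength_range range of the uniform draw for edge strengths.
#' @param basal_sd sd of per-TF basal drive.
#' @param patient_effect_sd,condition_effect_sd sds of additive per-TF
#'   patient and condition offsets entering the ODE drive.
#' @param obs_noise_sd sd of Gaussian observation noise on sampled activities.
#' @param init_sd sd of the random initial activity state of each series.
#' @param targets_per_tf dedicated target genes per TF in the regulon.
#' @param frac_repressed_targets fraction of regulon entries with mode -1.
#' @param activity_gain multiplicative gain linking TF activity to the
#'   log-scale mean of its targets' expression.
#' @param baseline_range range of per-gene basal log-expression offsets.
#' @param n_background_genes genes not controlled by any TF.
#' @param nb_dispersion negative-binomial dispersion (NB size = 1/dispersion).
#' @param library_size_range range of per-sample library-size factors.
#' @param euler_step fixed Euler integration step, in days.
#' @param x_cap absolute activity value beyond which integration aborts.
#' @param seed base seed for all draws.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_tfs = 25, edge_density = 0.08, frac_negative = 0.2,
                       frac_condition_specific = 0.2, n_patients = 3,
                       n_replicates = 2, days = c(1L, 4L, 8L, 11L, 14L),
                       decay_range = c(0.15, 0.4),
                       strength_range = c(0.8, 1.6), basal_sd = 0.2,
                       patient_effect_sd = 0.2, condition_effect_sd = 0.2,
                       obs_noise_sd = 0.1, init_sd = 1.0,
                       targets_per_tf = 10, frac_repressed_targets = 0.3,
                       activity_gain = 1.5, baseline_range = c(1, 4),
                       n_background_genes = 300, nb_dispersion = 0.1,
                       library_size_range = c(10, 30), euler_step = 0.05,
                       x_cap = 50, seed = 1L) {
  cfg <- as.list(environment())
  cfg$days <- sort(as.integer(days))
  stopifnot(
    cfg$n_tfs >= 2,
    cfg$edge_density >= 0, cfg$edge_density <= 1,
    all(diff(cfg$days) > 0),
    cfg$obs_noise_sd >= 0, cfg$patient_effect_sd >= 0,
    cfg$condition_effect_sd >= 0, cfg$basal_sd >= 0,
    cfg$targets_per_tf >= 1, cfg$nb_dispersion >= 0,
    cfg$euler_step > 0
  )
  if (cfg$euler_step >= min(diff(cfg$days)))
    stop("euler_step must be smaller than the smallest day gap")
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Sample a ground-truth signed TF-TF network
#'
#' Each ordered non-self TF pair is included independently with probability
#' `edge_density`; edges are inhibitory with probability `frac_negative` and
#' restricted to a single culture condition with probability
#' `frac_condition_specific` (split evenly between the two conditions).
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return list with `tfs` (character) and `edges` (data.frame regulator,
#'   target, strength, sign, scope).
#' @export
sample_ground_truth <- function(cfg, seed = cfg$seed) {
  if (cfg$n_tfs < 2) stop("need at least 2 TFs")
  tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  pairs <- expand.grid(regulator = tfs, target = tfs,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, , drop = FALSE]
  with_seed(substream(seed, 11L), {
    keep <- stats::runif(nrow(pairs)) < cfg$edge_density
    edges <- pairs[keep, , drop = FALSE]
    n <- nrow(edges)
    edges$strength <- stats::runif(n, cfg$strength_range[1], cfg$strength_range[2])
    edges$sign <- ifelse(stats::runif(n) < cfg$frac_negative, -1, 1)
    scoped <- stats::runif(n) < cfg$frac_condition_specific
    which_cond <- sample(c("autologous_only", "monoculture_only"), n,
                         replace = TRUE)
    edges$scope <- ifelse(scoped, which_cond, "both")
    rownames(edges) <- NULL
    list(tfs = tfs, edges = edges)
  })
}

# drive matrices per condition: W[i, j] = signed strength of edge j -> i
scope_matrices <- function(net) {
  tfs <- net$tfs
  n <- length(tfs)
  mk <- function(cond) {
    keep <- net$edges$scope %in% c("both", paste0(cond, "_only"))
    w <- matrix(0, n, n, dimnames = list(tfs, tfs))
    e <- net$edges[keep, , drop = FALSE]
    if (nrow(e))
      w[cbind(match(e$target, tfs), match(e$regulator, tfs))] <-
        e$strength * e$sign
    w
  }
  list(autologous = mk("autologous"), monoculture = mk("monoculture"))
}

#' Simulate TF activity time courses from a ground-truth network
#'
#' Per (patient, condition, replicate) series, integrates
#' `dx_i/dt = -alpha_i x_i + sum_j s_ij w_ij tanh(x_j) + b_i + u_{p,i} + v_{c,i}`
#' by fixed-step Euler from a random initial state; condition-scoped edges
#' contribute only in their condition. Observations are the trajectory at the
#' design days plus Gaussian noise.
#'
#' @param net a [sample_ground_truth()] result.
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return list with `activity` (TF x sample matrix of observed values),
#'   `design` ([sample_design()]), `trajectories` (list of dense series),
#'   `alpha` (true decay rates), and the effect vectors used.
#' @export
simulate_activities <- function(net, cfg, seed = cfg$seed) {
  if (cfg$euler_step >= min(diff(cfg$days)))
    stop("euler_step must be smaller than the smallest day gap")
  tfs <- net$tfs
  n <- length(tfs)
  W <- scope_matrices(net)
  conditions <- c("autologous", "monoculture")
  patients <- sprintf("p%d", seq_len(cfg$n_patients))
  with_seed(substream(seed, 22L), {
    alpha <- stats::runif(n, cfg$decay_range[1], cfg$decay_range[2])
    b <- stats::rnorm(n, 0, cfg$basal_sd)
    u <- matrix(stats::rnorm(n * cfg$n_patients, 0, cfg$patient_effect_sd),
                nrow = cfg$n_patients, dimnames = list(patients, tfs))
    v <- matrix(stats::rnorm(n * 2, 0, cfg$condition_effect_sd),
                nrow = 2, dimnames = list(conditions, tfs))
    t_grid <- seq(cfg$days[1], cfg$days[length(cfg$days)], by = cfg$euler_step)
    if (t_grid[length(t_grid)] < cfg$days[length(cfg$days)])
      t_grid <- c(t_grid, cfg$days[length(cfg$days)])
    design <- list(); cols <- list(); traj <- list()
    for (p in patients) for (cond in conditions) for (r in seq_len(cfg$n_replicates)) {
      x <- stats::rnorm(n, 0, cfg$init_sd)
      path <- matrix(NA_real_, n, length(t_grid), dimnames = list(tfs, NULL))
      path[, 1] <- x
      for (k in seq_len(length(t_grid) - 1L)) {
        h <- t_grid[k + 1L] - t_grid[k]
        drive <- W[[cond]] %*% tanh(x)
        dx <- -alpha * x + as.numeric(drive) + b + u[p, ] + v[cond, ]
        x <- x + h * dx
        if (any(!is.finite(x)) || any(abs(x) > cfg$x_cap))
          stop("activity trajectory exceeded |x| cap ", cfg$x_cap,
               "; unstable configuration")
        path[, k + 1L] <- x
      }
      obs_idx <- match(cfg$days, round(t_grid, 10))
      obs <- path[, obs_idx, drop = FALSE] +
        matrix(stats::rnorm(n * length(cfg$days), 0, cfg$obs_noise_sd),
               n, length(cfg$days))
      ids <- sprintf("%s_%s_r%d_d%02d", p, substr(cond, 1, 4), r, cfg$days)
      colnames(obs) <- ids
      cols[[length(cols) + 1L]] <- obs
      design[[length(design) + 1L]] <- data.frame(
        sample_id = ids, patient = p, condition = cond, day = cfg$days,
        replicate = r, stringsAsFactors = FALSE)
      traj[[sprintf("%s_%s_r%d", p, cond, r)]] <-
        list(time = t_grid, x = path)
    }
    dd <- do.call(rbind, design)
    activity <- do.call(cbind, cols)
    list(activity = activity,
         design = sample_design(dd$sample_id, dd$patient, dd$condition,
                                dd$day, dd$replicate),
         trajectories = traj, alpha = alpha, basal = b,
         patient_effects = u, condition_effects = v)
  })
}

#' Sample regulons (TF -> target genes) for the synthetic network
#'
#' Every TF receives `targets_per_tf` dedicated target genes, repressed with
#' probability `frac_repressed_targets`, weight 1; background genes belong to
#' no regulon.
#'
#' @param net a [sample_ground_truth()] result.
#' @param cfg a [sim_config()].
#' @param seed optional override.
#' @return list with `regulon` (a [regulon()]), `background_genes` and
#'   `truth` (data.frame target gene -> controlling tf + mode).
#' @export
sample_regulons <- function(net, cfg, seed = cfg$seed) {
  stopifnot(cfg$targets_per_tf >= 1)
  with_seed(substream(seed, 33L), {
    tf_idx <- rep(seq_along(net$tfs), each = cfg$targets_per_tf)
    genes <- sprintf("g_%s_%02d", net$tfs[tf_idx],
                     sequence(rep(cfg$targets_per_tf, length(net$tfs))))
    mode <- ifelse(stats::runif(length(genes)) < cfg$frac_repressed_targets,
                   -1, 1)
    reg <- regulon(net$tfs[tf_idx], genes, mode, 1)
    bg <- if (cfg$n_background_genes > 0)
      sprintf("bg%04d", seq_len(cfg$n_background_genes)) else character()
    list(regulon = reg, background_genes = bg,
         truth = data.frame(target = genes, tf = net$tfs[tf_idx],
                            mode = mode, stringsAsFactors = FALSE))
  })
}

#' Generate negative-binomial counts from TF activities
#'
#' Target gene g of TF j with mode m has mean
#' `mu_gs = softplus(beta0_g + m * activity_gain * x_js) * libsize_s`;
#' background genes have activity-independent means. Counts are drawn
#' negative-binomial with the configured dispersion.
#'
#' @param activities TF x sample activity matrix.
#' @param regulons a [sample_regulons()] result.
#' @param cfg a [sim_config()].
#' @param seed optional override.
#' @return list with `counts` (gene x sample integer matrix, see
#'   [expression_matrix()]) and `library_sizes`.
#' @export
expression_from_activities <- function(activities, regulons, cfg,
                                       seed = cfg$seed) {
  if (any(!is.finite(activities))) stop("non-finite activity values")
  truth <- regulons$truth
  genes <- c(truth$target, regulons$background_genes)
  n_s <- ncol(activities)
  with_seed(substream(seed, 44L), {
    libsize <- stats::runif(n_s, cfg$library_size_range[1],
                            cfg$library_size_range[2])
    beta0 <- stats::runif(length(genes), cfg$baseline_range[1],
                          cfg$baseline_range[2])
    names(beta0) <- genes
    eta <- matrix(rep(beta0, n_s), length(genes), n_s,
                  dimnames = list(genes, colnames(activities)))
    x <- activities[truth$tf, , drop = FALSE]
    eta[seq_len(nrow(truth)), ] <- eta[seq_len(nrow(truth)), ] +
      truth$mode * cfg$activity_gain * x
    mu <- softplus(eta) * matrix(rep(libsize, each = length(genes)),
                                 length(genes), n_s)
    counts <- matrix(
      if (cfg$nb_dispersion > 0)
        stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
      else stats::rpois(length(mu), lambda = mu),
      length(genes), n_s, dimnames = dimnames(mu))
    list(counts = expression_matrix(counts, "counts"),
         library_sizes = stats::setNames(libsize, colnames(activities)),
         baselines = beta0)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [sample_ground_truth()],
#' [simulate_activities()], [sample_regulons()] and
#' [expression_from_activities()] off a single seed.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return list with `truth_net`, `sim` (activities etc.), `regulons`,
#'   `counts`, `design`, `library_sizes`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = cfg$seed) {
  net <- sample_ground_truth(cfg, seed)
  sim <- simulate_activities(net, cfg, seed)
  regs <- sample_regulons(net, cfg, seed)
  expr <- expression_from_activities(sim$activity, regs, cfg, seed)
  list(truth_net = net, sim = sim, regulons = regs,
       counts = expr$counts, design = sim$design,
       library_sizes = expr$library_sizes)
}
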