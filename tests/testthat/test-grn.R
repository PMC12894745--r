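test_that("decay estimation follows the shifted log-range construction", {
  design <- toy_design(n_days = 5, n_reps = 1, conditions = "autologous")
  # constant series: alpha = 0
  act <- matrix(2, 1, nrow(design),
                dimnames = list("T1", design$sample_id))
  expect_equal(unname(estimate_decay(act, design)$per_tf), 0)

  # series spanning 0..8 over days 1..14: alpha = log(9)/13
  act2 <- rbind(T1 = seq(0, 8, length.out = nrow(design)))
  colnames(act2) <- design$sample_id
  expect_equal(unname(estimate_decay(act2, design)$per_tf), log(9) / 13)

  # pooled value is the median over TFs
  spans <- c(exp(0.1 * 13) - 1, exp(0.2 * 13) - 1, exp(0.3 * 13) - 1)
  act3 <- do.call(rbind, lapply(spans, function(s)
    seq(0, s, length.out = nrow(design))))
  dimnames(act3) <- list(c("a", "b", "c"), design$sample_id)
  expect_equal(estimate_decay(act3, design)$pooled, 0.2)
  expect_error(estimate_decay(act3[, 1, drop = FALSE], design[1, ]),
               "two time points")
})

test_that("a noiseless regulator chain is recovered by the tree ensemble", {
  # TF01 -> TF02, TF03 independent: TF01 must dominate TF02's incoming weights
  cfg <- sim_config(n_tfs = 3, obs_noise_sd = 0, basal_sd = 0,
                    patient_effect_sd = 0, condition_effect_sd = 0,
                    targets_per_tf = 5, n_background_genes = 20)
  net <- list(tfs = c("TF01", "TF02", "TF03"),
              edges = data.frame(regulator = "TF01", target = "TF02",
                                 strength = 1.2, sign = 1, scope = "both"))
  sim <- simulate_activities(net, cfg)
  dec <- estimate_decay(sim$activity, sim$design)
  hits <- vapply(1:5, function(s) {
    fit <- fit_dyn_network(sim$activity, sim$design, "autologous",
                           dec$pooled, n_trees = 200, seed = s)
    inc <- fit[fit$target == "TF02", ]
    inc$regulator[which.max(inc$weight)] == "TF01"
  }, logical(1))
  expect_true(all(hits))
})

test_that("degenerate activity matrices give empty or normalised weights", {
  design <- toy_design(n_days = 3, conditions = "autologous")
  flat <- matrix(1, 3, nrow(design),
                 dimnames = list(c("a", "b", "c"), design$sample_id))
  fit <- fit_dyn_network(flat, design, "autologous", alpha = 0.2,
                         n_trees = 50, seed = 1)
  expect_equal(nrow(fit), 0)

  set.seed(7)
  act <- matrix(rnorm(3 * nrow(design)), 3, nrow(design),
                dimnames = list(c("a", "b", "c"), design$sample_id))
  fit2 <- fit_dyn_network(act, design, "autologous", alpha = 0.2,
                          n_trees = 100, seed = 1)
  sums <- tapply(fit2$weight, fit2$target, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_false(any(fit2$regulator == fit2$target))
})

test_that("stability intersection keeps edges above threshold in every run", {
  mk <- function(...) {
    w <- c(...)
    data.frame(regulator = "a", target = paste0("t", seq_along(w)), weight = w)
  }
  runs <- replicate(10, mk(0.034, 0.02), simplify = FALSE)
  runs[[10]] <- mk(0.034, 0.005)   # second edge dips below 0.01 once
  out <- stability_intersect(runs, w_min = 0.01)
  expect_identical(out$target, "t1")
  expect_equal(out$weight, 0.034)

  # single run reduces to a plain threshold filter
  single <- stability_intersect(list(mk(0.5, 0.001)), w_min = 0.01)
  expect_identical(single$target, "t1")
  expect_error(stability_intersect(list()), "empty")
})

test_that("condition merge takes the union with max weight and tags", {
  a <- data.frame(regulator = c("x", "y"), target = c("y", "z"),
                  weight = c(0.02, 0.3))
  m <- data.frame(regulator = "x", target = "y", weight = 0.05)
  merged <- merge_conditions(a, m)
  xy <- merged[merged$regulator == "x", ]
  expect_equal(xy$weight, 0.05)
  expect_identical(xy$conditions, "autologous,monoculture")
  yz <- merged[merged$regulator == "y", ]
  expect_identical(yz$conditions, "autologous")
  empty <- merge_conditions(a[0, ], m[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("the correlation network applies threshold, sign and variance rules", {
  mk_tab <- function(scores) {
    cells <- expand.grid(patient = c("p1", "p2"), day_a = c(1, 4, 8),
                         stringsAsFactors = FALSE)
    do.call(rbind, lapply(names(scores), function(tf)
      data.frame(tf = tf, patient = cells$patient, condition = "autologous",
                 day_a = cells$day_a, day_b = cells$day_a + 3,
                 nes_raw = scores[[tf]], score = scores[[tf]], p = 0.01)))
  }
  base <- c(1, -2, 3, -1, 2, 0.5)
  tab <- mk_tab(list(A = base, B = base, C = -base,
                     D = c(0.9, 2.2, -0.6, 1.8, -2.0, 0.1),
                     E = rep(0, 6)))
  net <- diff_corr_network(tab, "autologous", cor_min = 0.5)
  key <- paste(net$tf_a, net$tf_b)
  expect_equal(net$cor[key == "A B"], 1)
  expect_equal(net$sign[key == "A B"], 1)
  expect_equal(net$cor[key == "A C"], -1)
  expect_equal(net$sign[key == "A C"], -1)
  expect_false(any(grepl("E", key)))   # zero-variance vector skipped
  low <- abs(cor(base, c(0.9, 2.2, -0.6, 1.8, -2.0, 0.1)))
  if (low < 0.5) expect_false("A D" %in% key)
})

test_that("the consensus keeps directed edges whose pair is correlated", {
  directed <- data.frame(regulator = c("i", "j", "k", "i"),
                         target = c("j", "i", "i", "z"),
                         weight = c(0.4, 0.3, 0.2, 0.9),
                         conditions = "autologous")
  corr <- data.frame(tf_a = "i", tf_b = "j", cor = -0.8, sign = -1)
  cons <- consensus_network(directed, corr)
  expect_equal(nrow(cons), 2)   # both orientations of {i, j} retained
  expect_true(all(cons$sign == -1))
  expect_true(all(paste(cons$regulator, cons$target) %in% c("i j", "j i")))
  # a pair with no directed edge contributes nothing
  corr2 <- rbind(corr, data.frame(tf_a = "a", tf_b = "b", cor = 0.9, sign = 1))
  expect_equal(nrow(consensus_network(directed, corr2)), 2)
  # consensus edge count is bounded by both parents
  expect_lte(nrow(cons), nrow(directed))
  expect_lte(nrow(cons), 2 * nrow(corr))
})
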