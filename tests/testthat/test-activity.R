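test_that("the enrichment score matches hand computations and its identities", {
  z <- c(g1 = 2, g2 = -2, g3 = 0.5)
  reg2 <- data.frame(tf = "T", target = c("g1", "g2"), mode = c(1, -1),
                     weight = 1)
  expect_equal(nes_score(z, reg2, min_targets = 1)$nes, 4 / sqrt(2))

  reg1 <- data.frame(tf = "T", target = "g1", mode = 1, weight = 1)
  expect_equal(nes_score(c(g1 = 3), reg1, min_targets = 1)$nes, 3)
  expect_equal(nes_score(c(g1 = 0, g2 = 0), reg2, min_targets = 1)$nes, 0)

  # linearity in the signature and antisymmetry under mode flip
  set.seed(4)
  for (i in 1:10) {
    zz <- setNames(rnorm(30), paste0("g", 1:30))
    reg <- data.frame(tf = "T", target = sample(names(zz), 8),
                      mode = sample(c(-1, 1), 8, TRUE),
                      weight = runif(8, 0.2, 1))
    a <- runif(1, -3, 3)
    expect_equal(nes_score(a * zz, reg)$nes, a * nes_score(zz, reg)$nes)
    flipped <- reg; flipped$mode <- -reg$mode
    expect_equal(nes_score(zz, flipped)$nes, -nes_score(zz, reg)$nes)
  }

  # too few measured targets: skipped
  expect_true(is.na(nes_score(z, reg2, min_targets = 3)$nes))
})

test_that("permutation p follows the add-one rule and its degenerate cases", {
  # observed NES = 0: every null tie-or-exceeds, p = 1
  z <- setNames(c(0, 0, rnorm(50)), paste0("g", 1:52))
  reg <- data.frame(tf = "T", target = c("g1", "g2"), mode = 1, weight = 1)
  res <- permutation_p(z, reg, min_targets = 2, n_perm = 1000, seed = 1)
  expect_equal(res$p, 1)

  # observed |NES| above every null: a single shuffled label can contribute
  # at most |z|max/sqrt(2) < observed, so p hits the add-one floor 1/1001
  z2 <- setNames(c(100, 100, rep(0, 9998)), paste0("g", 1:10000))
  reg2 <- data.frame(tf = "T", target = c("g1", "g2"), mode = 1, weight = 1)
  res2 <- permutation_p(z2, reg2, min_targets = 2, n_perm = 1000, seed = 1)
  expect_equal(res2$p, 1 / 1001)

  # p is never 0 and never above 1
  expect_gte(res2$p, 1 / 1001)
  expect_lte(res$p, 1)
})

test_that("per-sample activity scoring ranks constructed signals first", {
  set.seed(5)
  genes <- paste0("g", 1:60)
  std <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(genes, paste0("s", 1:4)))
  # TF "hot" owns the 6 most up-standardised genes of sample s1
  std[1:6, 1] <- 5
  reg <- rbind(
    data.frame(tf = "hot", target = genes[1:6], mode = 1, weight = 1),
    data.frame(tf = "cold", target = genes[7:12], mode = 1, weight = 1),
    data.frame(tf = "mix", target = genes[13:18], mode = 1, weight = 1))
  act <- activity_matrix(expression_matrix(std, "standardised"),
                         regulon(reg$tf, reg$target, reg$mode, reg$weight))
  expect_equal(names(which.max(act[, "s1"])), "hot")

  # all-zero sample: all NES 0
  std0 <- std; std0[, 2] <- 0
  act0 <- activity_matrix(expression_matrix(std0, "standardised"),
                          regulon(reg$tf, reg$target, reg$mode, reg$weight))
  expect_equal(unname(act0[, "s2"]), rep(0, 3))

  # deterministic: bit-equal reruns
  expect_identical(act, activity_matrix(
    expression_matrix(std, "standardised"),
    regulon(reg$tf, reg$target, reg$mode, reg$weight)))
})

test_that("differential activity localises a constructed jump and zeroes by p", {
  # 2 replicates x 3 days for one patient/condition; TF A's targets jump
  # between day 4 and day 8, everything else is flat noise
  set.seed(6)
  design <- toy_design(n_days = 3, conditions = "autologous")
  genes <- paste0("g", 1:80)
  m <- matrix(abs(rnorm(80 * nrow(design), 50, 1)), 80, nrow(design),
              dimnames = list(genes, design$sample_id))
  jump_samples <- design$sample_id[design$day >= 8]
  m[1:10, jump_samples] <- m[1:10, jump_samples] + 40
  reg <- rbind(
    data.frame(tf = "A", target = genes[1:10], mode = 1, weight = 1),
    data.frame(tf = "B", target = genes[41:50], mode = 1, weight = 1))
  reg <- regulon(reg$tf, reg$target, reg$mode, reg$weight)
  da <- differential_activity(m, design, reg, "p1", "autologous",
                              n_perm = 500, seed = 3)
  a48 <- da[da$tf == "A" & da$day_a == 4, ]
  expect_gt(a48$score, 0)
  expect_lt(a48$p, 0.05)
  expect_equal(da$score[da$tf == "A" & da$day_a == 1], 0)
  expect_equal(da$score[da$tf == "B" & da$day_a == 4], 0)

  # stored-score invariant: zero iff non-significant or zero raw score
  expect_true(all((da$score == 0) == (da$p > 0.05 | da$nes_raw == 0)))

  # identical expression at both days: score 0, p = 1
  m2 <- m
  for (d in c(4, 8)) {
    s <- design$sample_id[design$day == d]
    m2[, s] <- m2[, design$sample_id[design$day == 1]]
  }
  da2 <- differential_activity(m2, design, reg, "p1", "autologous",
                               n_perm = 200, seed = 3)
  expect_true(all(da2$score == 0))
  expect_true(all(da2$p == 1))
})

test_that("DA selection unions significant rows and records its tags", {
  tab <- data.frame(
    tf = c("A", "A", "B", "C"),
    patient = c("p1", "p2", "p1", "p3"),
    condition = c("autologous", "monoculture", "autologous", "autologous"),
    day_a = c(1, 4, 1, 8), day_b = c(4, 8, 4, 11),
    nes_raw = c(2, 1.5, 0.3, 1), score = c(2, 1.5, 0, 0),
    p = c(0.01, 0.03, 0.4, 0.2))
  sel <- select_da_tfs(tab)
  expect_identical(sel$tf, "A")
  expect_identical(sel$conditions, "autologous,monoculture")
  expect_identical(sel$patients, "p1,p2")
  expect_identical(sel$intervals, "d1-d4,d4-d8")
  expect_error(select_da_tfs(tab, alpha = 0), "no TF")
})

test_that("ORA of DA TFs plus targets delegates to the hypergeometric test", {
  reg <- regulon(c("A", "A", "B"), c("g1", "g2", "g3"), 1, 1)
  universe <- c("A", "B", "g1", "g2", "g3", "x1", "x2", "x3", "x4", "x5")
  sets <- list(hit = c("A", "g1", "g2"), miss = c("x4", "x5"))
  out <- ora_tf_targets("A", reg, sets, universe)
  expect_equal(out$k[out$set == "hit"], 3)
  expect_equal(out$k[out$set == "miss"], 0)
  expect_equal(out$p[out$set == "miss"], 1)
  oracle <- ora(c("A", "g1", "g2"), sets$hit, universe)
  expect_equal(out$p[out$set == "hit"], oracle$p)
  expect_equal(out$p_adj, bh_adjust(out$p))
})
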