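test_that("pairwise distance matrix matches direct recomputation", {
  set.seed(51)
  shapes <- array(rnorm(5 * 3 * 6), dim = c(5, 3, 6))
  D <- pairwise_distance_matrix(shapes)
  expect_equal(dim(D), c(6, 6))
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:6) for (j in 1:6)
    expect_equal(D[i, j], procrustes_distance(shapes[, , i], shapes[, , j]),
                 tolerance = 1e-12)

  same <- array(rep(shapes[, , 1], 4), dim = c(5, 3, 4))
  expect_true(all(pairwise_distance_matrix(same) == 0))

  two <- pairwise_distance_matrix(shapes[, , 1:2])
  expect_equal(two[1, 2], two[2, 1])
})

test_that("distance-matrix SS decomposition equals coordinate-space linear-model SS", {
  set.seed(52)
  dat <- toy_longitudinal(6, stages = c("T0", "T1"), k = 4)
  dat$design$group <- rep(c("a", "b"), each = 6)
  D <- as.matrix(dist(dat$Y))
  tab <- permanova(D, dat$design, n_perms = 99, seed = 1)
  oracle <- lm_seq_ss_oracle(dat$Y, dat$design$stage, dat$design$group)
  expect_equal(tab$SS[1:3], unname(oracle$ss), tolerance = 1e-9)
  expect_equal(tab$SS[4], oracle$ss_res, tolerance = 1e-9)
  # SS additivity
  expect_equal(sum(tab$SS[1:4]), tab$SS[5], tolerance = 1e-9)
  # partial R2 as defined from term and residual SS
  expect_equal(tab$partial_R2[1:3], tab$SS[1:3] / (tab$SS[1:3] + tab$SS[4]))
})

test_that("unrestricted decomposition agrees with vegan::adonis2", {
  set.seed(53)
  n <- 24
  Y <- matrix(rnorm(n * 6), n)
  design <- data.frame(subject_id = sprintf("S%02d", 1:n),  # one obs per subject
                       stage = factor(rep(c("T0", "T1", "T2"), each = 8)),
                       group = factor(rep(c("a", "b"), 12)))
  D <- as.matrix(dist(Y))
  tab <- permanova(D, design, n_perms = 199, seed = 2)
  ref <- vegan::adonis2(D ~ stage + group + stage:group, data = design,
                        permutations = 199, by = "terms")
  expect_equal(tab$SS[1:4], ref$SumOfSqs[1:4], tolerance = 1e-8)
  expect_equal(tab$pseudo_F[1:3], ref$F[1:3], tolerance = 1e-8)
})

test_that("degenerate inputs raise the documented errors", {
  design <- data.frame(subject_id = rep(c("A", "B", "C"), each = 2),
                       stage = rep(c("T0", "T1"), 3))
  D <- matrix(0, 6, 6)
  expect_error(permanova(D, design, n_perms = 99), "zero total sum of squares")
  expect_error(permutation_scheme("A", n_perms = 0), "n_perms")
})

test_that("exact enumeration is used for small within-subject groups and matches the oracle", {
  for (s in 1:5) {
    set.seed(600 + s)
    dat <- toy_longitudinal(5, stages = c("T0", "T1"), k = 3, stage_effect = 0.8)
    D <- as.matrix(dist(dat$Y))
    tab <- permanova(D, dat$design, n_perms = 9999, seed = 1)
    expect_true(attr(tab, "enumerated")[["stage"]])
    expect_equal(attr(tab, "n_perms")[["stage"]], 32L)
    p_oracle <- exact_perm_oracle(dat$Y, dat$design$subject_id, dat$design$stage)
    expect_equal(tab$p[1], p_oracle)
  }
})

test_that("permutation p-values are reproducible, seed-sensitive, and never zero", {
  set.seed(61)
  dat <- toy_longitudinal(12, stages = c("T0", "T1", "T2"), k = 5, stage_effect = 2)
  D <- as.matrix(dist(dat$Y))
  t1 <- permanova(D, dat$design, n_perms = 199, seed = 7)
  t2 <- permanova(D, dat$design, n_perms = 199, seed = 7)
  expect_identical(t1, t2)
  expect_true(all(t1$p[1] > 0))
  expect_gte(t1$p[1], 1 / 200)   # +1 convention bounds p away from zero

  t3 <- permanova(D, dat$design, n_perms = 199, seed = 8)
  expect_lt(abs(t3$p[1] - t1$p[1]), 0.1)  # Monte-Carlo error only
})

test_that("rejection rate is monotone in the injected stage effect", {
  effects <- c(0, 0.3, 1, 4)
  reps <- 15
  rate <- sapply(seq_along(effects), function(e) {
    rej <- 0
    for (r in 1:reps) {
      set.seed(1000 * e + r)
      dat <- toy_longitudinal(10, stages = c("T0", "T1", "T2"), k = 4,
                              stage_effect = effects[e], subject_sd = 1,
                              noise_sd = 0.5)
      D <- as.matrix(dist(dat$Y))
      tab <- permanova(D, dat$design, n_perms = 99, seed = r)
      rej <- rej + (tab$p[1] <= 0.05)
    }
    rej / reps
  })
  expect_true(all(diff(rate) >= -0.1))   # non-decreasing up to binomial noise
  expect_lt(rate[1], 0.35)
  expect_gt(rate[4], 0.9)
})

test_that("partial_r2 implements the coefficient of partial determination", {
  expect_equal(partial_r2(0, 5), 0)
  expect_equal(partial_r2(2, 8), 0.2)
  expect_error(partial_r2(0, 0), "undefined")
})

test_that("paper-faithful single-rule mode shuffles all terms within subject", {
  set.seed(71)
  dat <- toy_longitudinal(8, stages = c("T0", "T1"), k = 4)
  dat$design$group <- rep(c("a", "b"), each = 8)
  D <- as.matrix(dist(dat$Y))
  scheme <- permutation_scheme(dat$design$subject_id, n_perms = 99, seed = 1,
                               rules = c(stage = "within_subject",
                                         group = "within_subject",
                                         `stage:group` = "within_subject"))
  tab <- permanova(D, dat$design, scheme)
  # all three terms get p-values from the within-subject stream
  expect_true(all(tab$p[1:3] > 0 & tab$p[1:3] <= 1))
  # both modes agree on the decomposition itself, only p generation differs
  tab_mixed <- permanova(D, dat$design, n_perms = 99, seed = 1)
  expect_equal(tab$SS, tab_mixed$SS)
  expect_equal(tab$pseudo_F, tab_mixed$pseudo_F)
})

test_that("posthoc pairwise table has the stage-pair schema and sane values", {
  set.seed(81)
  dat <- toy_longitudinal(8, stages = c("T0", "T1", "T2"), k = 5, stage_effect = 1)
  post <- pairwise_posthoc(dat$shapes, dat$design, n_perms = 199, seed = 1)
  expect_identical(post$pair, c("T0-T1", "T0-T2", "T1-T2"))
  expect_true(all(post$pd >= 0))
  expect_true(all(post$p > 0 & post$p <= 1))
  expect_true(all(post$n_subjects == 8))

  # identical data relabelled as two stages: no effect, PD = 0, p = 1
  k <- 4
  base <- matrix(rnorm(8 * 3 * k), 8)
  Y <- rbind(base, base)
  design <- data.frame(subject_id = rep(sprintf("S%d", 1:8), 2),
                       stage = rep(c("T0", "T1"), each = 8))
  shapes <- array(t(Y), dim = c(k, 3, 16))
  post2 <- pairwise_posthoc(shapes, design, n_perms = 199, seed = 1)
  expect_equal(post2$pd, 0, tolerance = 1e-12)
  expect_equal(post2$p, 1)
})
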