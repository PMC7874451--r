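test_that("procrustes variance: trivial values and summation oracle", {
  set.seed(91)
  k <- 5
  a <- unit_center(random_config(k))
  same <- array(rep(a, 4), dim = c(k, 3, 4))
  expect_equal(unname(procrustes_variance(same, rep("g", 4))), 0)

  # two shapes at distance d: PV = d^2 / 4 under the 1/n convention
  b <- unit_center(random_config(k))
  d <- procrustes_distance(a, b)
  pv <- procrustes_variance(array(c(a, b), dim = c(k, 3, 2)), rep("g", 2))
  expect_equal(unname(pv), d^2 / 4, tolerance = 1e-12)

  shapes <- array(rnorm(k * 3 * 7), dim = c(k, 3, 7))
  pv <- procrustes_variance(shapes, rep("g", 7))
  Y <- t(matrix(shapes, k * 3, 7))
  mu <- colMeans(Y)
  oracle <- 0
  for (i in 1:7) oracle <- oracle + sum((Y[i, ] - mu)^2)
  expect_equal(unname(pv), oracle / 7, tolerance = 1e-12)

  expect_error(procrustes_variance(shapes, factor(rep("g", 7), levels = c("g", "h"))),
               "empty")
})

test_that("disparity test: identical groups give zero difference and p = 1", {
  set.seed(92)
  k <- 5
  block <- array(rnorm(k * 3 * 6), dim = c(k, 3, 6))
  shapes <- array(c(block, block), dim = c(k, 3, 12))
  groups <- rep(c("a", "b"), each = 6)
  res <- disparity_test(shapes, groups, n_perms = 199, seed = 3)
  expect_equal(res$table$delta_var, 0, tolerance = 1e-15)
  expect_equal(res$table$p, 1)
})

test_that("disparity test: singleton groups are reported but not tested", {
  set.seed(93)
  shapes <- array(rnorm(4 * 3 * 5), dim = c(4, 3, 5))
  groups <- c("a", "a", "a", "a", "b")
  expect_warning(res <- disparity_test(shapes, groups, n_perms = 99, seed = 1),
                 "size 1")
  expect_true(is.na(res$table$p))
  expect_equal(unname(res$variances["b"]), 0)
})

test_that("disparity test is deterministic given a seed", {
  set.seed(94)
  shapes <- array(rnorm(6 * 3 * 20), dim = c(6, 3, 20))
  groups <- rep(c("a", "b"), 10)
  r1 <- disparity_test(shapes, groups, n_perms = 199, seed = 5)
  r2 <- disparity_test(shapes, groups, n_perms = 199, seed = 5)
  expect_identical(r1, r2)
})

test_that("per-landmark analysis: zero effect and zero noise give zero magnitudes", {
  dat <- toy_longitudinal(6, stages = c("T0", "T1"), k = 5,
                          stage_effect = 0, noise_sd = 0)
  pl <- per_landmark_analysis(dat$shapes, dat$design, mm_scale = 100,
                              n_perms = 49, seed = 1)
  expect_equal(max(pl$displacements[["T0-T1"]]$magnitude_mm), 0, tolerance = 1e-10)
  expect_equal(pl$summary$mean_mm, 0, tolerance = 1e-10)
})

test_that("a single displaced landmark is recovered within GPA leakage tolerance", {
  tpl <- make_template(80)
  k <- nrow(tpl$coords)
  n_sub <- 15
  set.seed(95)
  target <- 11  # landmark pushed 2 mm in z between stages, same for all subjects
  confs <- list()
  design <- data.frame(subject_id = character(0), stage = character(0))
  for (s in 1:n_sub) {
    subj <- tpl$coords + matrix(rnorm(k * 3, sd = 0.05), k, 3)
    t1 <- subj
    t1[target, 3] <- t1[target, 3] + 2
    confs <- c(confs, list(subj, t1))
    design <- rbind(design, data.frame(subject_id = rep(sprintf("S%02d", s), 2),
                                       stage = c("T0", "T1")))
  }
  res <- gpa(confs)
  mm <- mean(res$centroid_sizes)
  pl <- per_landmark_analysis(res$shapes, design, mm_scale = mm,
                              n_perms = 99, seed = 2)
  est <- pl$displacements[["T0-T1"]]$magnitude_mm[target]

  # oracle skipping superimposition: the raw mean displacement is exactly 2 mm
  raw <- sapply(seq_len(n_sub), function(s) confs[[2 * s]][target, ] - confs[[2 * s - 1]][target, ])
  oracle <- sqrt(sum(rowMeans(raw)^2))
  expect_equal(oracle, 2, tolerance = 1e-12)
  expect_lt(abs(est - oracle) / oracle, 0.05)  # Pinocchio-effect leakage bound
  # the displaced landmark dominates the stage R2 map
  expect_equal(which.max(pl$stats$r2_stage), target)
})

test_that("per-landmark p-values are valid and BH adjustment is applied", {
  set.seed(96)
  dat <- toy_longitudinal(10, stages = c("T0", "T1"), k = 8, stage_effect = 0.6)
  pl <- per_landmark_analysis(dat$shapes, dat$design, mm_scale = 1,
                              n_perms = 99, seed = 3)
  expect_true(all(pl$stats$p_stage > 0 & pl$stats$p_stage <= 1))
  expect_equal(pl$stats$p_adj, p.adjust(pl$stats$p_stage, "BH"))
  expect_true(all(pl$stats$r2_stage >= 0 & pl$stats$r2_stage <= 1))
})

test_that("form analysis detects size-only change that shape analysis cannot", {
  set.seed(97)
  k <- 12
  base <- unit_center(random_config(k))
  n_sub <- 12
  shapes <- array(0, dim = c(k, 3, 2 * n_sub))
  sizes <- numeric(2 * n_sub)
  design <- data.frame(subject_id = rep(sprintf("S%02d", 1:n_sub), each = 2),
                       stage = rep(c("T0", "T1"), n_sub),
                       group = rep(c("a", "b"), each = n_sub))
  for (i in seq_len(2 * n_sub)) {
    # near-identical shapes; sizes grow by 10% between stages
    shapes[, , i] <- unit_center(base + matrix(rnorm(k * 3, sd = 1e-3), k, 3))
    sizes[i] <- (if (i %% 2 == 0) 110 else 100) + rnorm(1, sd = 0.5)
  }
  shape_tab <- permanova(pairwise_distance_matrix(shapes), design,
                         n_perms = 199, seed = 1)
  form <- run_form_analysis(shapes, sizes, design, n_perms = 199, seed = 1)
  expect_lt(form$permanova$p[1], 0.05)   # size change detected in form space
  expect_gt(shape_tab$p[1], 0.1)         # invisible to shape space
  # all sizes equal: form results equal shape results scaled by that size
  form_eq <- run_form_analysis(shapes2 <- array(rnorm(k * 3 * 2 * n_sub),
                                                dim = c(k, 3, 2 * n_sub)),
                               rep(100, 2 * n_sub), design,
                               n_perms = 99, seed = 4)
  shape_eq <- permanova(pairwise_distance_matrix(shapes2), design,
                        n_perms = 99, seed = 4)
  expect_equal(form_eq$permanova$pseudo_F[1:3], shape_eq$pseudo_F[1:3],
               tolerance = 1e-9)
  expect_equal(form_eq$permanova$p[1:3], shape_eq$p[1:3])
  expect_equal(form_eq$permanova$SS[1:3], shape_eq$SS[1:3] * 100^2,
               tolerance = 1e-6)
})
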