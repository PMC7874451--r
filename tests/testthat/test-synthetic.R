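test_that("template is exactly symmetric with labelled regions and valid anchors", {
  tpl <- make_template(120)
  expect_lt(max(abs(reflect_relabel(tpl$coords, tpl$symmetry) - tpl$coords)), 1e-12)
  expect_true(all(table(tpl$region_labels) > 0))
  expect_equal(nrow(tpl$coords), 2 * nrow(tpl$symmetry$pairs))  # k = 2 * k_half
  expect_equal(length(unique(tpl$anchor_indices)), 5)
  # anchor order: right exocanthus has x < 0, left x > 0, pronasale near midline
  ax <- tpl$coords[tpl$anchor_indices, 1]
  expect_lt(ax[1], 0); expect_gt(ax[2], 0)
  expect_lt(abs(ax[3]), 10)
  expect_error(make_template(20), "k_half")
})

test_that("nuisance transforms are fully removed by GPA when effects and noise are off", {
  tpl <- make_template(80)
  pars <- simulation_params(n_subjects = 5, group_sizes = c(all = 5),
                            effect_mm = c(buccal = 0, temporal = 0, labial = 0,
                                          nasal = 0, other = 0),
                            lower_lip_extra_mm = 0, subject_sd = 0, noise_sd = 0,
                            seed = 2)
  ch <- simulate_cohort(tpl, pars)
  res <- gpa(ch$configs)
  D <- pairwise_distance_matrix(res$shapes)
  expect_lt(max(D), 1e-9)
})

test_that("generated configurations are exactly symmetric before noise", {
  tpl <- make_template(80)
  pars <- simulation_params(n_subjects = 4, group_sizes = c(all = 4),
                            noise_sd = 0, max_rot_deg = 0, max_trans_mm = 0,
                            scale_range = c(1, 1), seed = 5)
  ch <- simulate_cohort(tpl, pars)
  for (i in seq_len(dim(ch$configs)[3])) {
    conf <- ch$configs[, , i]
    expect_lt(max(abs(reflect_relabel(conf, tpl$symmetry) - conf)), 1e-9)
  }
})

test_that("ground-truth PD: zero field, homogeneity, and pipeline convergence", {
  tpl <- make_template(80)
  pars0 <- simulation_params(n_subjects = 2, group_sizes = c(all = 2),
                             effect_mm = c(buccal = 0, temporal = 0, labial = 0,
                                           nasal = 0, other = 0),
                             lower_lip_extra_mm = 0, seed = 1)
  ch0 <- simulate_cohort(tpl, pars0)
  expect_equal(unname(ch0$truth$pd["T0-T1"]), 0, tolerance = 1e-12)

  # small fields so the shape-space map is in its linear regime
  base_field <- c(buccal = -0.3, temporal = -0.2, labial = 0.3, nasal = 0, other = 0)
  pars1 <- simulation_params(n_subjects = 2, group_sizes = c(all = 2), seed = 1,
                             effect_mm = base_field, lower_lip_extra_mm = 0.1)
  pars2 <- simulation_params(n_subjects = 2, group_sizes = c(all = 2), seed = 1,
                             effect_mm = 2 * base_field, lower_lip_extra_mm = 0.2)
  pd1 <- simulate_cohort(tpl, pars1)$truth$pd["T0-T1"]
  pd2 <- simulate_cohort(tpl, pars2)$truth$pd["T0-T1"]
  expect_equal(unname(pd2 / pd1), 2, tolerance = 1e-3)  # small-displacement linearity

  # pipeline PD converges to the ground truth as noise vanishes and n grows
  pars <- simulation_params(n_subjects = 25, group_sizes = c(all = 25),
                            subject_sd = 0.5, noise_sd = 0.01, seed = 9)
  ch <- simulate_cohort(tpl, pars)
  res <- gpa(ch$configs, include_reflections = TRUE, map = tpl$symmetry)
  sym <- symmetric_component(res)
  post <- pairwise_posthoc(sym, ch$design, n_perms = 99, seed = 1)
  est <- post$pd[post$pair == "T0-T1"]
  expect_lt(abs(est - ch$truth$pd["T0-T1"]) / ch$truth$pd["T0-T1"], 0.02)

  expect_error(ground_truth_pd(ch$truth, "T0-T9"), "unknown stage pair")
})

test_that("cumulative fields obey additivity and the PD triangle inequality", {
  tpl <- make_template(80)
  ch <- simulate_cohort(tpl, simulation_params(n_subjects = 3,
                                               group_sizes = c(all = 3), seed = 4))
  f <- ch$truth$pair_fields
  expect_equal(f[["T0-T2"]], f[["T0-T1"]] + f[["T1-T2"]], tolerance = 1e-12)
  expect_lte(ch$truth$pd["T0-T2"],
             ch$truth$pd["T0-T1"] + ch$truth$pd["T1-T2"] + 1e-12)
})

test_that("estimated Procrustes variance increases with landmark noise", {
  tpl <- make_template(80)
  pv <- sapply(c(0.1, 0.4, 1.2), function(ns) {
    ch <- simulate_cohort(tpl, simulation_params(n_subjects = 8,
                                                 group_sizes = c(all = 8),
                                                 subject_sd = 0, noise_sd = ns,
                                                 seed = 17))
    res <- gpa(ch$configs)
    unname(procrustes_variance(res$shapes, rep("g", dim(res$shapes)[3])))
  })
  expect_true(all(diff(pv) > 0))
})

test_that("default simulation reproduces the study design shape", {
  pars <- simulation_params()
  expect_equal(pars$n_subjects, 43)
  expect_equal(unname(pars$group_sizes), c(22, 21))
  expect_equal(pars$stages, c("T0", "T1", "T2"))
  ch <- simulate_cohort(make_template(60), pars)
  expect_equal(nrow(ch$design), 129)
  expect_equal(as.integer(table(ch$design$group)), c(66, 63))
  expect_s3_class(ch$design, "design_table")
})

test_that("meshes built from configurations support end-to-end mapping", {
  tpl <- make_template(100)
  # a noise-free subject whose face differs from the template by the stage
  # displacement field and a nuisance similarity transform
  ch <- simulate_cohort(tpl, simulation_params(n_subjects = 1,
                                               group_sizes = c(all = 1),
                                               subject_sd = 0, noise_sd = 0,
                                               seed = 23))
  conf0 <- ch$configs[, , 1]  # T0: a pure similarity transform of the template
  mesh0 <- mesh_from_landmarks(tpl, conf0)
  expect_equal(nrow(mesh0$vertices), nrow(tpl$coords))

  f <- tempfile(fileext = ".ply")
  write_mesh(mesh0, f)
  expect_lt(max(abs(read_mesh(f)$vertices - mesh0$vertices)), 1e-6)

  mapped0 <- map_template(tpl, mesh0, anchor_set(conf0[tpl$anchor_indices, ]))
  rms0 <- sqrt(mean(rowSums((mapped0$coords - conf0)^2)))
  expect_lt(rms0, 0.5)

  # a deformed stage (T2, ~1.3 mm field): the mapper stays on the surface and
  # beats plain similarity alignment of the template
  conf2 <- ch$configs[, , 3]
  mesh2 <- mesh_from_landmarks(tpl, conf2)
  anchors2 <- anchor_set(conf2[tpl$anchor_indices, ])
  mapped2 <- map_template(tpl, mesh2, anchors2)
  expect_lt(max(project_to_mesh(mapped2$coords, mesh2)$distance), 1e-8)
  tf <- similarity_align_anchors(tpl$coords[tpl$anchor_indices, ], anchors2$coords)
  naive <- apply_similarity(tf, tpl$coords)
  rms2 <- sqrt(mean(rowSums((mapped2$coords - conf2)^2)))
  rms_naive <- sqrt(mean(rowSums((naive - conf2)^2)))
  expect_lt(rms2, rms_naive)
})
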