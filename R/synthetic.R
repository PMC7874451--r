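#' Build a synthetic bilaterally symmetric quasi-landmark template
#'
#' Samples quasi-landmarks on a smooth face-like parametric patch (an
#' ellipsoidal shell with nasal, labial and orbital relief), on a structured
#' half-grid that is mirrored across x = 0 to give exact bilateral symmetry.
#' Region labels (buccal, temporal, labial, nasal, other) are assigned from
#' parametric zones; the five anchor indices are the landmarks nearest the
#' canonical anchor positions; the symmetry map and a triangulation come
#' from the mirrored-grid construction. All coordinates are in mm at
#' life-like facial scale.
#'
#' @param k_half number of landmarks per half-face (>= 50); the template has
#'   k = 2 * k_half landmarks (there is no shared midline column, so k is
#'   exactly even). The default half-grid (10 x 36) gives k = 720, a
#'   one-tenth-scale analogue of a 7160-point anthropometric mask; pass
#'   k_half = 3580 for full scale.
#' @return Object of class \code{quasi_template}: \code{coords} (k x 3, mm),
#'   \code{anchor_indices} (length 5, fixed anchor order),
#'   \code{region_labels}, \code{symmetry} (a \code{\link{symmetry_map}}),
#'   \code{faces} (triangulation), \code{normals} (outward unit normals).
#' @export
make_template <- function(k_half = 360L) {
  if (k_half < 50L) stop("k_half too small to cover all facial regions (need >= 50)")
  nu <- max(4L, round(sqrt(k_half / 3.6)))
  nv <- max(10L, round(k_half / nu))
  k_half <- nu * nv

  s <- (seq_len(nu) - 0.5) / nu          # lateral, midline-exclusive
  t <- (seq_len(nv) - 0.5) / nv          # vertical
  grid <- expand.grid(i = seq_len(nv), j = seq_len(nu))   # col-major within half
  y <- 140 * (t[grid$i] - 0.5)
  halfw <- 78 * sqrt(pmax(0.02, 1 - (y / 80)^2))
  x <- s[grid$j] * halfw
  z <- face_depth(x, y)
  left <- cbind(x = x, y = y, z = z)
  right <- left
  right[, 1L] <- -right[, 1L]
  coords <- rbind(left, right)
  k <- 2L * k_half

  pairs <- cbind(seq_len(k_half), k_half + seq_len(k_half))
  sym <- symmetry_map(pairs, integer(0), k)

  faces_half <- grid_faces(nv, nu)
  faces <- rbind(faces_half,
                 faces_half[, c(1L, 3L, 2L)] + k_half,   # mirrored half, flipped winding
                 stitch_faces(nv, k_half))
  storage.mode(faces) <- "integer"
  normals <- vertex_normals(coords, faces)

  ax <- abs(coords[, 1L]); yy <- coords[, 2L]
  region <- rep("other", k)
  region[ax >= 28 & yy > -48 & yy < 28] <- "buccal"
  region[ax >= 38 & yy >= 28] <- "temporal"
  region[ax < 30 & yy >= -55 & yy <= -22] <- "labial"
  region[ax < 15 & yy > -22 & yy < 18] <- "nasal"
  region <- factor(region, levels = c("buccal", "temporal", "labial", "nasal", "other"))
  if (any(table(region) == 0L))
    stop("k_half too small: empty facial region(s) ",
         paste(levels(region)[table(region) == 0L], collapse = ", "))

  canon <- rbind(exocanthion_r = c(-45, 25), exocanthion_l = c(45, 25),
                 pronasale = c(0, -5), cheilion_r = c(-23, -38),
                 cheilion_l = c(23, -38))
  anchor_indices <- apply(canon, 1L, function(p) {
    which.min((coords[, 1L] - p[1L])^2 + (coords[, 2L] - p[2L])^2)
  })
  if (anyDuplicated(anchor_indices))
    stop("k_half too small: anchor positions collapse onto the same landmark")

  structure(list(coords = coords, anchor_indices = as.integer(anchor_indices),
                 region_labels = region, symmetry = sym, faces = faces,
                 normals = normals),
            class = "quasi_template")
}

# smooth facial depth relief (mm)
face_depth <- function(x, y) {
  55 * sqrt(pmax(0, 1 - (x / 85)^2 - (y / 95)^2)) +
    16 * exp(-(x^2 / 130 + (y + 5)^2 / 180)) +
    3 * exp(-(x^2 / 420 + (y + 38)^2 / 70)) -
    2.5 * exp(-((abs(x) - 32)^2 / 160 + (y - 28)^2 / 120))
}

# triangulation of an nv x nu column-major grid
grid_faces <- function(nv, nu) {
  id <- function(i, j) (j - 1L) * nv + i
  f <- list()
  for (j in seq_len(nu - 1L)) for (i in seq_len(nv - 1L)) {
    f[[length(f) + 1L]] <- c(id(i, j), id(i + 1L, j), id(i, j + 1L))
    f[[length(f) + 1L]] <- c(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
  }
  do.call(rbind, f)
}

# stitch the two innermost columns (j = 1 of each half) across the midline
stitch_faces <- function(nv, k_half) {
  l <- seq_len(nv)            # left-half column j = 1
  r <- k_half + seq_len(nv)   # right-half column j = 1
  f <- list()
  for (i in seq_len(nv - 1L)) {
    f[[length(f) + 1L]] <- c(l[i], r[i], l[i + 1L])
    f[[length(f) + 1L]] <- c(r[i], r[i + 1L], l[i + 1L])
  }
  do.call(rbind, f)
}

# area-weighted outward unit vertex normals (+z oriented)
vertex_normals <- function(coords, faces) {
  e1 <- coords[faces[, 2L], , drop = FALSE] - coords[faces[, 1L], , drop = FALSE]
  e2 <- coords[faces[, 3L], , drop = FALSE] - coords[faces[, 1L], , drop = FALSE]
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  fn <- fn * sign(ifelse(fn[, 3L] == 0, 1, fn[, 3L]))   # orient toward +z
  vn <- matrix(0, nrow(coords), 3L)
  for (c3 in 1:3) {
    acc <- fn
    vn <- vn + rowsum_expand(acc, faces[, c3], nrow(coords))
  }
  vn / pmax(sqrt(rowSums(vn^2)), 1e-12)
}

rowsum_expand <- function(values, idx, n) {
  out <- matrix(0, n, ncol(values))
  agg <- rowsum(values, idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Simulation parameters for a synthetic longitudinal cohort
#'
#' Defaults reproduce the design of a 43-subject, three-stage (T0/T1/T2)
#' orthodontic cohort split 22/21 into extraction and non-extraction groups,
#' with a region-localized normal-direction stage displacement field
#' (buccal and temporal invagination, labial protrusion with extra lower-lip
#' displacement), smooth symmetric per-subject shape effects, iid landmark
#' noise, and nuisance similarity transforms. The second-interval field is
#' one sixth of the first by default; \code{target_mean_mm} rescales either
#' interval field to a prescribed mean per-landmark magnitude.
#'
#' @param n_subjects number of subjects.
#' @param stages ordered stage labels.
#' @param group_sizes named integer vector of subjects per group (sums to
#'   \code{n_subjects}); use a single group for a one-group design.
#' @param effect_mm named amplitudes (mm, along outward normals; negative =
#'   invagination) of the first-interval field per region.
#' @param lower_lip_extra_mm additional protrusion for labial landmarks in
#'   the lower lip zone.
#' @param t1_t2_scale ratio of the second-interval field to the first.
#' @param target_mean_mm optional named vector \code{c(t0_t1=, t1_t2=)}
#'   rescaling the interval fields to exact mean per-landmark magnitudes.
#' @param subject_sd per-coordinate mm scale of the smooth symmetric
#'   per-subject deformation.
#' @param noise_sd iid per-coordinate landmark noise (mm).
#' @param max_rot_deg,max_trans_mm,scale_range nuisance similarity transform
#'   ranges (applied per observation, removed later by GPA).
#' @param group_effect_mm group-by-stage effect amplitude (default 0: no
#'   treatment-modality effect).
#' @param seed master seed.
#' @return List of class \code{simulation_params}.
#' @export
simulation_params <- function(n_subjects = 43L,
                              stages = c("T0", "T1", "T2"),
                              group_sizes = c(extraction = 22L, non_extraction = 21L),
                              effect_mm = c(buccal = -1.5, temporal = -1.0,
                                            labial = 1.5, nasal = 0, other = 0),
                              lower_lip_extra_mm = 0.5,
                              t1_t2_scale = 1 / 6,
                              target_mean_mm = c(t0_t1 = NA_real_, t1_t2 = NA_real_),
                              subject_sd = 1.5,
                              noise_sd = 0.2,
                              max_rot_deg = 15,
                              max_trans_mm = 50,
                              scale_range = c(0.9, 1.1),
                              group_effect_mm = 0,
                              seed = 1L) {
  if (sum(group_sizes) != n_subjects)
    stop("group sizes must sum to n_subjects")
  if (subject_sd < 0 || noise_sd < 0) stop("standard deviations must be >= 0")
  structure(as.list(environment()), class = "simulation_params")
}

# region-localized normal-direction displacement field (mm), smoothed and
# exactly symmetrized
stage_field <- function(template, effect_mm, lower_lip_extra_mm, sigma = 8) {
  amp <- as.numeric(effect_mm[as.character(template$region_labels)])
  amp[is.na(amp)] <- 0
  lower_lip <- template$region_labels == "labial" & template$coords[, 2L] < -40
  amp[lower_lip] <- amp[lower_lip] + lower_lip_extra_mm
  # smooth the amplitude over the surface to avoid region-edge steps
  # (chunked so full-scale templates never allocate a k x k matrix)
  X <- template$coords
  sq <- rowSums(X^2)
  k <- nrow(X)
  sm <- numeric(k)
  for (start in seq(1L, k, by = 1000L)) {
    ix <- start:min(start + 999L, k)
    D2 <- outer(sq[ix], sq, `+`) - 2 * X[ix, , drop = FALSE] %*% t(X)
    W <- exp(-pmax(D2, 0) / (2 * sigma^2))
    sm[ix] <- as.numeric(W %*% amp) / rowSums(W)
  }
  amp <- sm
  field <- template$normals * amp
  symmetrize_field(field, template$symmetry)
}

# average a vector field with its mirrored, relabelled copy
symmetrize_field <- function(field, map) {
  ref <- field[map$perm, , drop = FALSE]
  ref[, 1L] <- -ref[, 1L]
  (field + ref) / 2
}

mean_magnitude <- function(field) mean(sqrt(rowSums(field^2)))

#' Simulate a longitudinal quasi-landmark cohort with known ground truth
#'
#' Each observation is built as template + smooth symmetric per-subject
#' deformation + cumulative stage displacement field + iid noise, followed
#' by a random nuisance similarity transform (removed later by GPA). The
#' exact displacement fields applied are stored as ground truth. With all
#' effects and noise at zero, superimposed shapes are identical.
#'
#' @param template a \code{\link{make_template}} template.
#' @param params a \code{\link{simulation_params}} list.
#' @return List of class \code{synthetic_cohort}: \code{design} (design
#'   table, subject-major/stage-minor row order), \code{configs}
#'   (k x 3 x n array, mm, rows matching the design), \code{truth}
#'   (stage-pair fields in mm, implied PDs, per-subject fields),
#'   \code{template}, \code{params}.
#' @export
simulate_cohort <- function(template, params = simulation_params()) {
  stopifnot(inherits(template, "quasi_template"))
  k <- nrow(template$coords)
  stages <- params$stages
  ns <- length(stages)
  n_sub <- params$n_subjects
  set.seed(params$seed)

  d1 <- stage_field(template, params$effect_mm, params$lower_lip_extra_mm)
  if (is.finite(params$target_mean_mm["t0_t1"]) && mean_magnitude(d1) > 0)
    d1 <- d1 * params$target_mean_mm["t0_t1"] / mean_magnitude(d1)
  d2 <- d1 * params$t1_t2_scale
  if (is.finite(params$target_mean_mm["t1_t2"]) && mean_magnitude(d2) > 0)
    d2 <- d2 * params$target_mean_mm["t1_t2"] / mean_magnitude(d2)

  # cumulative displacement at each stage: 0, d1, d1 + d2, d1 + 2 d2, ...
  cum <- vector("list", ns)
  cum[[1L]] <- matrix(0, k, 3L)
  if (ns >= 2L) cum[[2L]] <- d1
  if (ns >= 3L) for (i in 3:ns) cum[[i]] <- cum[[i - 1L]] + d2
  names(cum) <- stages

  groups <- rep(names(params$group_sizes), params$group_sizes)
  subject_ids <- sprintf("S%03d", seq_len(n_sub))

  n <- n_sub * ns
  configs <- array(NA_real_, dim = c(k, 3L, n))
  design <- data.frame(subject_id = rep(subject_ids, each = ns),
                       stage = rep(stages, times = n_sub),
                       group = rep(groups, each = ns),
                       stringsAsFactors = FALSE)
  subject_fields <- vector("list", n_sub)
  names(subject_fields) <- subject_ids

  row <- 0L
  for (s in seq_len(n_sub)) {
    f_s <- random_subject_field(template, params$subject_sd)
    subject_fields[[s]] <- f_s
    grp_amp <- if (groups[s] == names(params$group_sizes)[1L]) params$group_effect_mm else 0
    for (t_i in seq_len(ns)) {
      row <- row + 1L
      base <- template$coords + f_s + cum[[t_i]] * (1 + grp_amp)
      noise <- matrix(stats::rnorm(k * 3L, sd = params$noise_sd), k, 3L)
      configs[, , row] <- random_nuisance(base + noise, params)
    }
  }

  pair_fields <- list()
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    pair_fields[[paste(stages[i], stages[j], sep = "-")]] <-
      cum[[j]] - cum[[i]]
  }
  truth <- structure(list(template_coords = template$coords,
                          cumulative = cum, pair_fields = pair_fields,
                          subject_fields = subject_fields),
                     class = "ground_truth")
  truth$pd <- vapply(names(pair_fields), function(p) ground_truth_pd(truth, p), 0)

  structure(list(design = validate_design(design, stages), configs = configs,
                 truth = truth, template = template, params = params),
            class = "synthetic_cohort")
}

# smooth symmetric per-subject radial-basis deformation (mm)
random_subject_field <- function(template, subject_sd, n_centers = 20L, rho = 25) {
  k <- nrow(template$coords)
  if (subject_sd == 0) return(matrix(0, k, 3L))
  centers <- template$coords[sample.int(k, n_centers), , drop = FALSE]
  amps <- matrix(stats::rnorm(n_centers * 3L), n_centers, 3L)
  D2 <- outer(rowSums(template$coords^2), rowSums(centers^2), `+`) -
    2 * template$coords %*% t(centers)
  phi <- exp(-pmax(D2, 0) / (2 * rho^2))
  f <- phi %*% amps
  f <- symmetrize_field(f, template$symmetry)
  rms <- sqrt(mean(f^2))
  if (rms > 0) f <- f * subject_sd / rms
  f
}

# random similarity nuisance transform of one configuration
random_nuisance <- function(coords, params) {
  ang <- stats::runif(1L, 0, params$max_rot_deg) * pi / 180
  ax <- stats::rnorm(3L)
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3L], ax[2L], ax[3L], 0, -ax[1L], -ax[2L], ax[1L], 0), 3L, 3L)
  R <- diag(3L) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  sc <- stats::runif(1L, params$scale_range[1L], params$scale_range[2L])
  tr <- stats::runif(3L, -params$max_trans_mm, params$max_trans_mm)
  sc * coords %*% t(R) + rep(tr, each = nrow(coords))
}

#' Procrustes distance implied by the true displacement field
#'
#' Superimposes the two noise-free stage-mean configurations (template plus
#' cumulative displacement) and returns their Procrustes distance — the
#' ground-truth value the full pipeline should recover as noise vanishes.
#'
#' @param truth the \code{truth} element of a \code{\link{simulate_cohort}}
#'   result.
#' @param pair stage pair label, e.g. \code{"T0-T1"}.
#' @return Dimensionless Procrustes distance.
#' @export
ground_truth_pd <- function(truth, pair) {
  stages <- strsplit(pair, "-", fixed = TRUE)[[1L]]
  if (length(stages) != 2L || !all(stages %in% names(truth$cumulative)))
    stop("unknown stage pair '", pair, "'")
  a <- truth$template_coords + truth$cumulative[[stages[1L]]]
  b <- truth$template_coords + truth$cumulative[[stages[2L]]]
  res <- gpa(list(a, b))
  procrustes_distance(res$shapes[, , 1L], res$shapes[, , 2L])
}

#' Mesh from a landmark configuration and a template triangulation
#'
#' Builds a surface mesh whose vertices are the configuration points and
#' whose faces come from the template triangulation — the synthetic stand-in
#' for a subject's raw facial scan, letting the template-mapping stage be
#' tested end to end.
#'
#' @param template a \code{\link{make_template}} template.
#' @param configuration a \code{landmark_configuration} or k x 3 matrix.
#' @return A \code{\link{surface_mesh}}.
#' @export
mesh_from_landmarks <- function(template, configuration) {
  coords <- if (inherits(configuration, "landmark_configuration"))
    configuration$coords else as_coord_matrix(configuration)
  if (nrow(coords) != nrow(template$coords))
    stop("configuration size does not match template")
  surface_mesh(coords, template$faces)
}

#' @export
print.quasi_template <- function(x, ...) {
  cat("quasi_template:", nrow(x$coords), "landmarks,", nrow(x$faces), "faces\n")
  print(table(x$region_labels))
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort:", x$params$n_subjects, "subjects x",
      length(x$params$stages), "stages,", nrow(x$template$coords), "landmarks\n")
  cat("  groups:", paste(names(x$params$group_sizes), x$params$group_sizes,
                         sep = "=", collapse = ", "), "\n")
  cat("  true stage-pair PDs:",
      paste(names(x$truth$pd), format(x$truth$pd, digits = 3), collapse = ", "), "\n")
  invisible(x)
}
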