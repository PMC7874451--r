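#' Per-landmark permutation analysis
#'
#' Localizes shape change by running the same repeated-measures model used
#' for the whole face on the 3 coordinates of each quasi-landmark
#' separately: sequential SS for stage (+ group + interaction when present),
#' partial R-squared of the stage term, a within-subject permutation p-value
#' per landmark (raw, with Benjamini-Hochberg adjusted values alongside),
#' and per stage pair the mean displacement vector and its magnitude in mm.
#'
#' Because the per-landmark distances are Euclidean, the distance-matrix
#' decomposition coincides with the coordinate-space linear-model sums of
#' squares, which is what is computed here (it is identical and much
#' cheaper for thousands of landmarks).
#'
#' @param shapes k x 3 x n array of superimposed shape coordinates, ordered
#'   as the design rows.
#' @param design data.frame with \code{subject_id}, \code{stage} and
#'   optionally \code{group}.
#' @param mm_scale factor converting shape units to mm; conventionally the
#'   grand mean centroid size of the dataset.
#' @param n_perms number of within-subject permutations for the stage term.
#' @param seed permutation seed.
#' @return Object of class \code{per_landmark_stats}: \code{stats}
#'   (data.frame landmark, r2_stage, p_stage, p_adj), \code{displacements}
#'   (per stage pair: k x 3 mm vectors and k magnitudes),
#'   \code{summary} (per pair: mean/sd/median magnitude, mm), and
#'   \code{mm_scale}.
#' @export
per_landmark_analysis <- function(shapes, design, mm_scale = 1,
                                  n_perms = 999L, seed = 1L) {
  design <- as.data.frame(design)
  stage <- droplevels(as.factor(design$stage))
  group <- if (!is.null(design$group)) droplevels(as.factor(design$group)) else factor(rep("all", nrow(design)))
  Y <- shapes_to_matrix(shapes)
  n <- nrow(Y)
  k <- ncol(Y) / 3L
  if (nrow(design) != n) stop("design and shape array sizes differ")

  with_group <- nlevels(group) > 1L
  X1 <- cbind(1, indicator(stage))
  X3 <- if (with_group)
    cbind(X1, indicator(group), indicator(interaction(stage, group, drop = TRUE)))
  else X1
  q0 <- qr(matrix(1, n, 1L)); q1 <- qr(X1); q3 <- qr(X3)
  Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
  Q1 <- qr.Q(q1)[, seq_len(q1$rank), drop = FALSE]
  Q3 <- qr.Q(q3)[, seq_len(q3$rank), drop = FALSE]
  df_stage <- q1$rank - q0$rank
  df_res <- n - q3$rank

  # column index of landmark j: (j, k + j, 2k + j)
  land_of_col <- rep(seq_len(k), times = 3L)
  by_landmark <- function(colvals) {
    as.numeric(rowsum(colvals, land_of_col))
  }

  col_ss <- function(Q, Ym) colSums((crossprod(Q, Ym))^2)
  total_col <- colSums(Y^2) - col_ss(Q0, Y)

  ss_stage_obs <- by_landmark(col_ss(Q1, Y) - col_ss(Q0, Y))
  ss_res_obs <- by_landmark(total_col - (col_ss(Q3, Y) - col_ss(Q0, Y)))
  F_obs <- (ss_stage_obs / df_stage) / (ss_res_obs / df_res)
  r2 <- partial_r2(ss_stage_obs, ss_res_obs)

  bi <- block_index(as.character(design$subject_id))
  set.seed(seed)
  cnt <- numeric(k)
  ftol <- 1e-8 * pmax(abs(F_obs), 1)
  for (b in seq_len(n_perms)) {
    pi <- sample_within(bi, n)
    Yp <- Y[pi, , drop = FALSE]
    ss_stage_b <- by_landmark(col_ss(Q1, Yp) - col_ss(Q0, Yp))
    ss_res_b <- by_landmark(total_col - (col_ss(Q3, Yp) - col_ss(Q0, Yp)))
    Fb <- (ss_stage_b / df_stage) / (ss_res_b / df_res)
    cnt <- cnt + (Fb >= F_obs - ftol)
  }
  p_raw <- (cnt + 1) / (n_perms + 1)
  p_adj <- stats::p.adjust(p_raw, method = "BH")

  lv <- levels(stage)
  displacements <- list()
  summaries <- list()
  for (i in seq_len(length(lv) - 1L)) for (j in (i + 1L):length(lv)) {
    a <- lv[i]; bstg <- lv[j]
    delta <- colMeans(Y[stage == bstg, , drop = FALSE]) -
      colMeans(Y[stage == a, , drop = FALSE])
    vec <- matrix(delta, k, 3L, dimnames = list(NULL, c("x", "y", "z"))) * mm_scale
    mag <- sqrt(rowSums(vec^2))
    pair <- paste(a, bstg, sep = "-")
    displacements[[pair]] <- list(vectors_mm = vec, magnitude_mm = mag)
    summaries[[pair]] <- data.frame(pair = pair,
                                    mean_mm = mean(mag), sd_mm = stats::sd(mag),
                                    median_mm = stats::median(mag))
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL

  structure(list(stats = data.frame(landmark = seq_len(k), r2_stage = r2,
                                    p_stage = p_raw, p_adj = p_adj),
                 displacements = displacements, summary = summary,
                 mm_scale = mm_scale, n_perms = n_perms),
            class = "per_landmark_stats")
}

#' @export
print.per_landmark_stats <- function(x, ...) {
  cat("Per-landmark stage analysis (", nrow(x$stats), " landmarks, ",
      x$n_perms, " permutations, mm scale ", format(x$mm_scale, digits = 6),
      ")\n", sep = "")
  cat("significant at raw p < 0.05:", sum(x$stats$p_stage < 0.05), "\n")
  print.data.frame(format(x$summary, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Summarize per-landmark displacement magnitudes for a stage pair
#'
#' @param per_landmark a \code{\link{per_landmark_analysis}} result.
#' @param pair stage pair label, e.g. \code{"T0-T1"}.
#' @param breaks number of histogram bins.
#' @return List with \code{mean_mm}, \code{sd_mm}, \code{median_mm} and a
#'   \code{histogram} (output of \code{\link[graphics]{hist}}, not plotted).
#' @export
summarize_magnitudes <- function(per_landmark, pair, breaks = 20L) {
  if (!pair %in% names(per_landmark$displacements))
    stop("unknown stage pair '", pair, "'; available: ",
         paste(names(per_landmark$displacements), collapse = ", "))
  mag <- per_landmark$displacements[[pair]]$magnitude_mm
  list(mean_mm = mean(mag), sd_mm = stats::sd(mag),
       median_mm = stats::median(mag),
       histogram = graphics::hist(mag, breaks = breaks, plot = FALSE))
}

#' Shape-and-size (form) analysis
#'
#' Applies the whole shape machinery in form space: shape coordinates are
#' multiplied by their centroid sizes, so distances are in mm and size
#' differences re-enter the analysis. Returns the main-effects PERMANOVA
#' table, pairwise post-hoc comparisons and the stage-by-group disparity
#' test, mirroring the shape-space outputs.
#'
#' @param shapes k x 3 x n array of superimposed shape coordinates.
#' @param sizes numeric vector of centroid sizes (mm), one per shape.
#' @param design data.frame with \code{subject_id}, \code{stage},
#'   \code{group}.
#' @param scheme optional \code{\link{permutation_scheme}}.
#' @param n_perms,seed used when \code{scheme} is NULL.
#' @return List with \code{forms} (k x 3 x n array, mm), \code{permanova},
#'   \code{posthoc}, \code{disparity}.
#' @export
run_form_analysis <- function(shapes, sizes, design, scheme = NULL,
                              n_perms = 10000L, seed = 1L) {
  n <- dim(shapes)[3L]
  if (length(sizes) != n) stop("need one centroid size per shape")
  if (any(sizes <= 0)) stop("centroid sizes must be positive")
  forms <- shapes
  for (i in seq_len(n)) forms[, , i] <- to_form(shapes[, , i], sizes[i])
  d <- pairwise_distance_matrix(forms)
  tab <- permanova(d, design, scheme, n_perms, seed)
  post <- pairwise_posthoc(forms, design, n_perms, seed)
  disp <- NULL
  if (!is.null(design$group) && nlevels(droplevels(as.factor(design$group))) >= 1L) {
    gg <- interaction(design$group, design$stage, sep = ":", drop = TRUE)
    disp <- disparity_test(forms, gg, n_perms, seed)
  }
  list(forms = forms, permanova = tab, posthoc = post, disparity = disp)
}
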