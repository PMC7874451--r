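#' Pipeline run configuration
#'
#' Collects everything one end-to-end analysis needs: the input cohort (a
#' \code{\link{simulate_cohort}} object, or a design CSV whose \code{file}
#' column points at per-observation configuration CSVs plus a template
#' prefix), the output directory, permutation counts, seed and significance
#' level, and switches for the optional analysis stages.
#'
#' @param output_dir directory for the report bundle (created if missing).
#' @param cohort optional in-memory \code{synthetic_cohort}.
#' @param design_csv,template_prefix file-based input: design table CSV and
#'   template prefix (see \code{\link{read_template}}); ignored when
#'   \code{cohort} is given.
#' @param n_perms permutations for whole-face tests (>= 99).
#' @param perlandmark_perms permutations for the per-landmark tests.
#' @param seed master seed for all permutation streams.
#' @param alpha significance level in (0, 1).
#' @param form,per_landmark,disparity logical switches for the optional
#'   stages.
#' @param make_plots write box-plot/histogram PDFs of per-landmark
#'   magnitudes.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(output_dir, cohort = NULL, design_csv = NULL,
                       template_prefix = NULL, n_perms = 999L,
                       perlandmark_perms = 499L, seed = 1L, alpha = 0.05,
                       form = TRUE, per_landmark = TRUE, disparity = TRUE,
                       make_plots = FALSE) {
  if (n_perms < 99L) stop("n_perms must be >= 99")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(cohort) && (is.null(design_csv) || is.null(template_prefix)))
    stop("provide either an in-memory cohort or design_csv + template_prefix")
  structure(list(output_dir = output_dir, cohort = cohort,
                 design_csv = design_csv, template_prefix = template_prefix,
                 n_perms = as.integer(n_perms),
                 perlandmark_perms = as.integer(perlandmark_perms),
                 seed = as.integer(seed), alpha = alpha, form = form,
                 per_landmark = per_landmark, disparity = disparity,
                 make_plots = make_plots),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   \code{\link{run_config}}.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full longitudinal morphometric pipeline
#'
#' Orchestrates symmetric-component GPA, shape and form PERMANOVA (main
#' effects and pairwise post-hoc), per-landmark localization with heatmap
#' mesh export (R-squared, -log10 p, displacement magnitude, pink
#' significance mask), and stage-by-modality disparity tests, writing a
#' report bundle of CSVs, ASCII-PLY heatmaps and a structured JSON-lines
#' run log. All randomness derives from the configured seed, so a re-run
#' with the same configuration reproduces the bundle's CSV/PLY files byte
#' for byte. Any stage failure aborts the run and removes partial outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list with the computed tables and result objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  log_path <- file.path(out, "run_log.jsonl")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)

  emit <- function(path) {
    created <<- c(created, path)
    path
  }
  log_step <- function(step, t0, outputs = character(0)) {
    rec <- list(step = step,
                elapsed_s = round(as.numeric(proc.time()["elapsed"]) - t0, 3),
                seed = config$seed,
                outputs = as.list(basename(outputs)),
                md5 = as.list(unname(tools::md5sum(outputs))))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), log_con)
  }
  run_stage <- function(name, expr) {
    t0 <- as.numeric(proc.time()["elapsed"])
    res <- tryCatch(expr, error = function(e) {
      unlink(created)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  # ---- input ----
  t0 <- as.numeric(proc.time()["elapsed"])
  inputs <- run_stage("input", {
    if (!is.null(config$cohort)) {
      ch <- config$cohort
      list(design = ch$design, configs = ch$configs, template = ch$template)
    } else {
      design <- read_design(config$design_csv)
      if (is.null(design$file)) stop("design table needs a 'file' column")
      template <- read_template(config$template_prefix)
      k <- nrow(template$coords)
      configs <- array(NA_real_, c(k, 3L, nrow(design)))
      for (i in seq_len(nrow(design)))
        configs[, , i] <- read_configuration(design$file[i])$coords
      list(design = design, configs = configs, template = template)
    }
  })
  design <- inputs$design
  template <- inputs$template
  log_step("input", t0)

  # ---- superimposition ----
  t0 <- as.numeric(proc.time()["elapsed"])
  sup <- run_stage("superimposition", {
    res <- gpa(inputs$configs, include_reflections = TRUE, map = template$symmetry)
    list(result = res, shapes = symmetric_component(res),
         mm_scale = mean(res$centroid_sizes))
  })
  log_step("superimposition", t0)
  shapes <- sup$shapes
  mm_scale <- sup$mm_scale

  scheme <- permutation_scheme(design$subject_id, config$n_perms, config$seed)

  # ---- main-effects tables (shape, and form when enabled) ----
  t0 <- as.numeric(proc.time()["elapsed"])
  tabs <- run_stage("permanova", {
    d_shape <- pairwise_distance_matrix(shapes)
    shape_tab <- permanova(d_shape, design, scheme)
    form_res <- NULL
    if (config$form)
      form_res <- run_form_analysis(shapes, sup$result$centroid_sizes, design,
                                    scheme, config$n_perms, config$seed)
    list(shape = shape_tab, form = form_res)
  })
  table1 <- merge_main_effects(tabs$shape,
                               if (config$form) tabs$form$permanova else NULL)
  p1 <- emit(file.path(out, "table1.csv"))
  utils::write.csv(table1, p1, row.names = FALSE)
  log_step("permanova", t0, p1)

  # ---- pairwise post-hoc ----
  t0 <- as.numeric(proc.time()["elapsed"])
  post <- run_stage("posthoc", {
    sh <- pairwise_posthoc(shapes, design, config$n_perms, config$seed)
    fo <- if (config$form) tabs$form$posthoc else NULL
    merge_posthoc(sh, fo)
  })
  p2 <- emit(file.path(out, "table2.csv"))
  utils::write.csv(post, p2, row.names = FALSE)
  log_step("posthoc", t0, p2)

  # ---- disparity ----
  table3 <- NULL
  if (config$disparity) {
    t0 <- as.numeric(proc.time()["elapsed"])
    table3 <- run_stage("disparity", {
      gg <- interaction(design$group, design$stage, sep = ":", drop = TRUE)
      sh <- disparity_test(shapes, gg, config$n_perms, config$seed)
      fo <- if (config$form) tabs$form$disparity else NULL
      merge_disparity(sh, fo, design)
    })
    p3 <- emit(file.path(out, "table3.csv"))
    utils::write.csv(table3, p3, row.names = FALSE)
    log_step("disparity", t0, p3)
  }

  # ---- per-landmark localization + heatmaps ----
  perlm <- NULL
  if (config$per_landmark) {
    t0 <- as.numeric(proc.time()["elapsed"])
    perlm <- run_stage("per_landmark", {
      per_landmark_analysis(shapes, design, mm_scale,
                            config$perlandmark_perms, config$seed)
    })
    p4 <- emit(file.path(out, "perlandmark.csv"))
    utils::write.csv(perlm$stats, p4, row.names = FALSE)
    p4b <- emit(file.path(out, "perlandmark_summary.csv"))
    utils::write.csv(perlm$summary, p4b, row.names = FALSE)

    heat <- run_stage("heatmaps", {
      mean_mm <- apply(shapes, c(1, 2), mean) * mm_scale
      hm_mesh <- surface_mesh(mean_mm, template$faces)
      paths <- c(emit(file.path(out, "heatmap_r2.ply")),
                 emit(file.path(out, "heatmap_neglog10p.ply")),
                 emit(file.path(out, "heatmap_mask.ply")))
      write_colored_mesh(hm_mesh, perlm$stats$r2_stage, paths[1L],
                         palette = "Viridis")
      write_colored_mesh(hm_mesh, -log10(perlm$stats$p_stage), paths[2L],
                         palette = "Viridis")
      sig <- perlm$stats$p_stage <= config$alpha
      write_mask_mesh(hm_mesh, sig, paths[3L])
      for (pair in names(perlm$displacements)) {
        pm <- emit(file.path(out, sprintf("heatmap_magnitude_%s.ply", pair)))
        write_colored_mesh(hm_mesh, perlm$displacements[[pair]]$magnitude_mm,
                           pm, palette = "Blue-Red 3")
        paths <- c(paths, pm)
      }
      writeLines(jsonlite::toJSON(
        list(alpha = config$alpha, n_significant = sum(sig),
             mm_scale = mm_scale), auto_unbox = TRUE, digits = NA), log_con)
      paths
    })
    log_step("per_landmark", t0, c(p4, p4b, heat))

    if (config$make_plots) {
      t0 <- as.numeric(proc.time()["elapsed"])
      pp <- emit(file.path(out, "magnitudes.pdf"))
      run_stage("plots", plot_magnitudes(perlm, pp))
      log_step("plots", t0, pp)
    }
  }

  invisible(list(design = design, gpa = sup$result, shapes = shapes,
                 mm_scale = mm_scale, table1 = table1, table2 = post,
                 table3 = table3, per_landmark = perlm,
                 form = tabs$form, output_dir = out, files = created))
}

merge_main_effects <- function(shape_tab, form_tab) {
  out <- data.frame(term = shape_tab$term, df = shape_tab$df,
                    shape_SS = shape_tab$SS,
                    shape_partial_R2 = shape_tab$partial_R2,
                    shape_p = shape_tab$p)
  if (!is.null(form_tab)) {
    out$form_SS <- form_tab$SS
    out$form_partial_R2 <- form_tab$partial_R2
    out$form_p <- form_tab$p
  }
  out
}

merge_posthoc <- function(shape_post, form_post) {
  out <- data.frame(pair = shape_post$pair, n_subjects = shape_post$n_subjects,
                    shape_pd = shape_post$pd,
                    shape_partial_R2 = shape_post$partial_R2,
                    shape_p = shape_post$p)
  if (!is.null(form_post)) {
    m <- match(out$pair, form_post$pair)
    out$form_pd_mm <- form_post$pd[m]
    out$form_partial_R2 <- form_post$partial_R2[m]
    out$form_p <- form_post$p[m]
  }
  out
}

# Table-3 layout: per treatment modality, stage-pair variance differences
merge_disparity <- function(shape_disp, form_disp, design) {
  groups <- levels(droplevels(as.factor(design$group)))
  stages <- levels(droplevels(as.factor(design$stage)))
  rows <- list()
  for (g in groups) {
    for (i in seq_len(length(stages) - 1L)) for (j in (i + 1L):length(stages)) {
      a <- paste(g, stages[i], sep = ":")
      b <- paste(g, stages[j], sep = ":")
      key <- paste(a, b, sep = "-")
      sel <- shape_disp$table$pair == key | shape_disp$table$pair == paste(b, a, sep = "-")
      if (!any(sel)) next
      row <- data.frame(group = g, pair = paste(stages[i], stages[j], sep = "-"),
                        shape_delta_var = shape_disp$table$delta_var[sel][1L],
                        shape_p = shape_disp$table$p[sel][1L])
      if (!is.null(form_disp)) {
        fsel <- form_disp$table$pair == key | form_disp$table$pair == paste(b, a, sep = "-")
        row$form_delta_var <- form_disp$table$delta_var[fsel][1L]
        row$form_p <- form_disp$table$p[fsel][1L]
      }
      rows[[key]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# box plot + histogram of per-landmark magnitudes per stage pair
plot_magnitudes <- function(perlm, path) {
  grDevices::pdf(path, width = 8, height = 4)
  on.exit(grDevices::dev.off(), add = TRUE)
  for (pair in names(perlm$displacements)) {
    mag <- perlm$displacements[[pair]]$magnitude_mm
    graphics::par(mfrow = c(1, 2))
    graphics::boxplot(mag, main = paste("Magnitude", pair), ylab = "mm")
    graphics::hist(mag, breaks = 20, main = "", xlab = "mm")
  }
  invisible(path)
}
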