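#' Default pipeline configuration
#'
#' Nested list mirroring the config file sections: `simulate` (arguments of
#' [synth_params()]), `vbm` (smoothing and the two GLM thresholds),
#' `mediation`, `stats`. Any subset can be overridden by a user config (YAML
#' file or list); unspecified entries keep these defaults.
#'
#' @param seed Top-level run seed; stage seeds derive from it.
#' @return A nested list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(),
    vbm = list(
      fwhm_mm = 8,
      group = list(p_fwe = 0.05, min_extent = 100L, n_perm = 199L),
      alps_glm = list(p_voxel = 0.001, min_extent = 100L, adjust_etiv = TRUE),
      connectivity = 18L
    ),
    mediation = list(
      radius_mm = 4, left_only = TRUE, max_seeds = 3L, B = 1000L,
      alpha = 0.05, outcomes = c("casi_total", "short_term_memory"),
      group = "YOAD", mediator_maps = "smoothed"
    ),
    stats = list(adjust = "none",
                 correlates = c("age", "education"))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration
#'
#' @param config `NULL` (defaults), a YAML file path, or a nested list of
#'   overrides merged onto [default_pipeline_config()].
#' @return The merged config list.
#' @export
read_pipeline_config <- function(config = NULL) {
  base <- default_pipeline_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(base, config)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

config_synth_params <- function(cfg) {
  sim <- cfg$simulate
  if (!is.null(sim$grid) && !inherits(sim$grid, "volume_grid")) {
    sim$grid <- volume_grid(unlist(sim$grid$shape),
                            unlist(sim$grid$voxel_size))
  }
  sim$seed <- cfg$seed
  do.call(synth_params, sim)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Runs the whole case-control workflow end to end: simulate the cohort; compute
#' per-subject ALPS indices from the tensor volumes; compare ALPS between
#' groups; smooth GM maps (8 mm FWHM); run the group-atrophy GLM (voxel-wise
#' max-T permutation FWE, cluster extent > 100 voxels) and the
#' ALPS-coherence GLM (uncorrected p < 0.001, extent > 100, eTIV-adjusted);
#' intersect the two cluster maps; place 4-mm sphere seeds at the
#' ALPS-coherence peaks (left hemisphere by default); extract per-subject
#' seed GM volumes; and run bias-corrected bootstrap mediation of
#' ALPS -> seed volume -> cognition per seed and outcome. Deterministic
#' given the config seed.
#'
#' @param config See [read_pipeline_config()].
#' @param out_dir Optional run directory; when given, all tables (TSV), stat
#'   maps (NIfTI), a markdown summary and `run.log` are written there.
#' @return An `alps_pipeline` list: `cohort` (with ALPS columns), `truth`,
#'   `alps_group` (group comparison row), `group_stat`/`alps_stat` (stat
#'   maps), `group_fwe_p` (corrected p volume), `clusters_group`,
#'   `clusters_alps` (tibbles), `overlap` (mask + count), `seeds`,
#'   `mediation` (tibble per seed x outcome), `mediation_fits`, `tables`
#'   (group comparison + regressions), `correlations`, `config`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- read_pipeline_config(config)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), line))
    message(line)
  }

  note("stage simulate: seed ", cfg$seed)
  sim <- stage_guard("simulate", {
    params <- config_synth_params(cfg)
    simulate_subjects(params, keep_volumes = FALSE)
  })
  n <- nrow(sim$cohort)
  grid <- sim$grid
  nvox <- prod(grid$shape)

  note("stage alps: ", n, " subjects")
  alps_tab <- stage_guard("alps", {
    dplyr::bind_cols(
      tibble::tibble(id = sim$cohort$id),
      dplyr::bind_rows(lapply(seq_len(n), function(i) {
        compute_alps(sim$volume_fn(i, "tensor"), sim$masks)
      }))
    )
  })
  cohort <- dplyr::left_join(sim$cohort, alps_tab, by = "id")
  alps_group <- group_compare(cohort, "alps_bilateral")

  note("stage vbm: smoothing ", cfg$vbm$fwhm_mm, " mm FWHM")
  Y_raw <- matrix(NA_real_, n, nvox)
  Y_smooth <- matrix(NA_real_, n, nvox)
  for (i in seq_len(n)) {
    gm <- sim$volume_fn(i, "gm")
    Y_raw[i, ] <- as.vector(gm$values)
    Y_smooth[i, ] <- as.vector(smooth_array(gm$values, cfg$vbm$fwhm_mm,
                                            grid$voxel_size))
  }
  attr(Y_raw, "grid") <- grid
  attr(Y_smooth, "grid") <- grid
  mask <- gm_analysis_mask(Y_smooth)
  note("analysis mask: ", sum(mask), " voxels")

  note("stage vbm: group contrast (max-T FWE, ", cfg$vbm$group$n_perm,
       " permutations)")
  res <- stage_guard("vbm_group", {
    design_g <- design_matrix(cohort, ~ group)
    contrast_g <- -as.numeric(colnames(design_g) == "groupYOAD")  # CTL > YOAD
    fwe_threshold_maxT(Y_smooth, design_g, contrast_g,
                       n_perm = cfg$vbm$group$n_perm, seed = cfg$seed + 1L,
                       mask = mask)
  })
  group_stat <- attr(res, "stat_map")
  group_fwe_p <- res
  clusters_group <- cluster_table(
    group_stat, p_voxel = cfg$vbm$group$p_fwe,
    min_extent = cfg$vbm$group$min_extent, p_map = group_fwe_p,
    connectivity = cfg$vbm$connectivity)
  mask_group <- cluster_mask(group_stat, p_voxel = cfg$vbm$group$p_fwe,
                             min_extent = cfg$vbm$group$min_extent,
                             p_map = group_fwe_p,
                             connectivity = cfg$vbm$connectivity)

  note("stage vbm: ALPS-coherence GLM (uncorrected p < ",
       cfg$vbm$alps_glm$p_voxel, ", k > ", cfg$vbm$alps_glm$min_extent, ")")
  alps_stat <- stage_guard("vbm_alps", {
    fml <- if (isTRUE(cfg$vbm$alps_glm$adjust_etiv)) {
      ~ alps_bilateral + etiv
    } else {
      ~ alps_bilateral
    }
    voxelwise_glm(Y_smooth, design_matrix(cohort, fml), "alps_bilateral",
                  mask = mask)
  })
  clusters_alps <- cluster_table(
    alps_stat, p_voxel = cfg$vbm$alps_glm$p_voxel,
    min_extent = cfg$vbm$alps_glm$min_extent,
    connectivity = cfg$vbm$connectivity)
  mask_alps <- cluster_mask(alps_stat, p_voxel = cfg$vbm$alps_glm$p_voxel,
                            min_extent = cfg$vbm$alps_glm$min_extent,
                            connectivity = cfg$vbm$connectivity)
  overlap <- overlap_mask(mask_group, mask_alps)
  note("cluster-map overlap: ", overlap$n_voxels, " voxels")

  note("stage mediation")
  med <- stage_guard("mediation", {
    run_mediation_stage(cfg, cohort, clusters_alps, grid,
                        if (cfg$mediation$mediator_maps == "smoothed") Y_smooth else Y_raw)
  })
  for (ln in med$notes) note(ln)

  note("stage stats")
  tables <- stage_guard("stats", {
    yoad <- dplyr::filter(cohort, .data$group == "YOAD")
    scores <- intersect(cognitive_score_info()$test, names(cohort))
    reg <- dplyr::bind_rows(lapply(scores, function(s) {
      cognition_regression(yoad, s)
    }))
    reg$p_adjusted <- stats::p.adjust(reg$p_value, method = cfg$stats$adjust)
    list(group_comparison = cohort_tables(cohort)$group_comparison,
         alps_regression = reg)
  })
  correlations <- stage_guard("stats", {
    yoad <- dplyr::filter(cohort, .data$group == "YOAD")
    dplyr::bind_rows(lapply(
      intersect(cognitive_score_info()$test, names(cohort)),
      function(s) spearman_partial(yoad, "alps_bilateral", s,
                                   cfg$stats$correlates)))
  })

  out <- structure(
    list(cohort = cohort, truth = sim$truth, alps = alps_tab,
         alps_group = alps_group, group_stat = group_stat,
         group_fwe_p = group_fwe_p, alps_stat = alps_stat,
         clusters_group = clusters_group, clusters_alps = clusters_alps,
         cluster_mask_group = mask_group, cluster_mask_alps = mask_alps,
         overlap = overlap, seeds = med$seeds, seed_volumes = med$seed_volumes,
         mediation = med$table, mediation_fits = med$fits,
         tables = tables, correlations = correlations,
         config = cfg, grid = grid, masks = sim$masks, log = log_lines),
    class = "alps_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

stage_guard <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

run_mediation_stage <- function(cfg, cohort, clusters_alps, grid, Y) {
  mc <- cfg$mediation
  notes <- character(0)
  peaks <- clusters_alps
  if (isTRUE(mc$left_only)) peaks <- dplyr::filter(peaks, .data$laterality == "L")
  # one seed per cluster: its top peak
  peaks <- peaks |>
    dplyr::group_by(.data$cluster) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$t)) |>
    utils::head(mc$max_seeds)
  empty <- tibble::tibble(
    seed = character(), outcome = character(), n = integer(),
    a = numeric(), a_p = numeric(), b = numeric(), b_p = numeric(),
    c = numeric(), c_p = numeric(), c_prime = numeric(), c_prime_p = numeric(),
    indirect = numeric(), ci_lower = numeric(), ci_upper = numeric(),
    classification = character()
  )
  if (nrow(peaks) == 0L) {
    notes <- c(notes, "no eligible cluster peaks: mediation skipped")
    return(list(table = empty, fits = list(), seeds = peaks,
                seed_volumes = NULL, notes = notes))
  }
  voxvol <- prod(grid$voxel_size)
  dat <- cohort
  fits <- list()
  rows <- list()
  seed_cols <- character(0)
  for (si in seq_len(nrow(peaks))) {
    seed <- sphere_mask(c(peaks$x[si], peaks$y[si], peaks$z[si]),
                        mc$radius_mm, grid)
    col <- sprintf("seed_vol_c%d", peaks$cluster[si])
    seed_cols <- c(seed_cols, col)
    dat[[col]] <- drop(Y[, which(as.vector(seed$mask)), drop = FALSE] %*%
                         rep(voxvol, sum(seed$mask)))
    for (outc in mc$outcomes) {
      sub <- dat[dat$group == mc$group, ]
      fit <- mediate(sub, x = "alps_bilateral", m = col, y = outc,
                     covariates = mc$covariates, B = mc$B, alpha = mc$alpha,
                     seed = cfg$seed + 2L + si)
      fits[[paste(col, outc, sep = ".")]] <- fit
      pd <- fit$paths
      pe <- function(p) pd$estimate[pd$path == p]
      pp <- function(p) pd$p_value[pd$path == p]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seed = col, outcome = outc, n = fit$n,
        a = pe("a"), a_p = pp("a"), b = pe("b"), b_p = pp("b"),
        c = pe("c"), c_p = pp("c"),
        c_prime = pe("c_prime"), c_prime_p = pp("c_prime"),
        indirect = fit$indirect, ci_lower = fit$ci_lower,
        ci_upper = fit$ci_upper, classification = fit$classification
      )
      notes <- c(notes, sprintf("%s ~ %s: indirect %.3g [%.3g, %.3g], %s",
                                outc, col, fit$indirect, fit$ci_lower,
                                fit$ci_upper, fit$classification))
    }
  }
  list(table = dplyr::bind_rows(rows), fits = fits, seeds = peaks,
       seed_volumes = dat[c("id", seed_cols)], notes = notes)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f), progress = FALSE)
  w(res$cohort, "cohort.tsv")
  w(res$truth, "truth.tsv")
  w(res$alps, "alps.tsv")
  w(res$alps_group, "alps_group.tsv")
  w(res$clusters_group, "clusters_group.tsv")
  w(res$clusters_alps, "clusters_alps.tsv")
  w(res$mediation, "mediation.tsv")
  w(res$tables$group_comparison, "group_compare.tsv")
  w(res$tables$alps_regression, "alps_regression.tsv")
  w(res$correlations, "correlations.tsv")
  tvol <- function(s) scalar_volume(ifelse(is.na(s$t), 0, s$t), s$grid)
  write_volume(tvol(res$group_stat), file.path(out_dir, "tmap_group.nii.gz"))
  write_volume(tvol(res$alps_stat), file.path(out_dir, "tmap_alps.nii.gz"))
  pv <- res$group_fwe_p
  write_volume(scalar_volume(ifelse(is.na(pv$values), 1, pv$values), pv$grid),
               file.path(out_dir, "fwe_p_group.nii.gz"))
  write_volume(res$overlap$mask, file.path(out_dir, "overlap_mask.nii.gz"))
  writeLines(pipeline_summary_md(res), file.path(out_dir, "summary.md"))
  writeLines(res$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

pipeline_summary_md <- function(res) {
  g <- res$alps_group
  med_lines <- if (nrow(res$mediation) == 0) {
    "- no eligible seeds"
  } else {
    sprintf("- %s via %s: indirect %.3g [%.3g, %.3g] -> %s",
            res$mediation$outcome, res$mediation$seed, res$mediation$indirect,
            res$mediation$ci_lower, res$mediation$ci_upper,
            res$mediation$classification)
  }
  c("# Synthetic ALPS pipeline summary", "",
    sprintf("- Subjects: %d CTL, %d YOAD", g$n1 + g$n2 - sum(res$cohort$group == "YOAD"),
            sum(res$cohort$group == "YOAD")),
    sprintf("- Bilateral ALPS: CTL %.3f +/- %.3f vs YOAD %.3f +/- %.3f (Student t = %.2f, p = %.3g)",
            g$mean1, g$sd1, g$mean2, g$sd2, g$t, g$p_value),
    sprintf("- Group-atrophy clusters (voxel FWE, k > %d): %d",
            res$config$vbm$group$min_extent,
            length(unique(res$clusters_group$cluster))),
    sprintf("- ALPS-coherence clusters (p < %g, k > %d): %d",
            res$config$vbm$alps_glm$p_voxel, res$config$vbm$alps_glm$min_extent,
            length(unique(res$clusters_alps$cluster))),
    sprintf("- Overlap of the two cluster maps: %d voxels", res$overlap$n_voxels),
    "", "## Mediation (bias-corrected bootstrap)", med_lines)
}

#' @export
print.alps_pipeline <- function(x, ...) {
  cat(pipeline_summary_md(x), sep = "\n")
  invisible(x)
}
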