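# End-to-end orchestration: simulate -> serial detection + dedup -> region
# assignment -> NND -> clustering -> orientation -> group statistics, from a
# single config, writing a self-describing report bundle. Stages communicate
# only through the declared file formats so each stage is testable in
# isolation; re-running from the emitted resolved config reproduces the
# bundle byte-identically.

#' Build a pipeline configuration
#'
#' @param seed master seed; every stage derives its sub-seed from it.
#' @param n_brains brains to simulate.
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "detect", "nnd", "cluster", "orient", "stats")`.
#'   Downstream stages require `"simulate"` (or `cells_csv`).
#' @param cells_csv optional: path to an existing multi-brain cell table
#'   used instead of the simulator.
#' @param k_range candidate cluster numbers.
#' @param n_init k-means restarts per k.
#' @param grid_size NND CDF grid resolution.
#' @param imaging a [serial_imaging_config()] for the detection stage.
#' @param migration a [migration_config()] for the orientation stage (its
#'   seed derives from `seed`).
#' @param brain_config a [synthetic_brain_config()]; its seed is overridden
#'   by `seed`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_brains = 3L,
                            stages = c("simulate", "detect", "nnd",
                                       "cluster", "orient", "stats"),
                            cells_csv = NULL,
                            k_range = 2:10, n_init = 10L, grid_size = 256L,
                            imaging = serial_imaging_config(),
                            migration = migration_config(),
                            brain_config = NULL) {
  known <- c("simulate", "detect", "nnd", "cluster", "orient", "stats")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(brain_config)) {
    brain_config <- synthetic_brain_config(seed = seed, n_brains = n_brains)
  } else {
    brain_config$seed <- as.integer(seed)
    brain_config$n_brains <- as.integer(n_brains)
  }
  needs_cells <- intersect(stages, c("detect", "nnd", "cluster", "stats"))
  if (length(needs_cells) && !("simulate" %in% stages) && is.null(cells_csv)) {
    stop("stage(s) ", paste(needs_cells, collapse = ", "),
         " enabled but no cell input: enable 'simulate' or give cells_csv",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_brains = as.integer(n_brains),
                 stages = stages, cells_csv = cells_csv, k_range = k_range,
                 n_init = as.integer(n_init),
                 grid_size = as.integer(grid_size),
                 imaging = imaging, migration = migration,
                 brain_config = brain_config),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order and writes per-stage outputs
#' (CSV/JSON) plus a resolved-config JSON and a plain-text log (seeds and
#' record counts, no timestamps) to `out_dir`. Deterministic given the
#' config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) the report: a named list of per-stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("thalamap pipeline, seed %d", config$seed),
                 sprintf("stages: %s", paste(config$stages, collapse = ", ")))
  report <- list(seed = config$seed, stages = config$stages)

  # --- cells ---------------------------------------------------------------
  brains <- NULL
  if ("simulate" %in% config$stages) {
    brains <- simulate_brain_series(config$brain_config)
    all_cells <- do.call(rbind, lapply(brains, `[[`, "cells"))
    write_cells(all_cells, file.path(out_dir, "cells.csv"))
    log_lines <- c(log_lines,
                   sprintf("simulate: %d brains, %d cells", length(brains),
                           nrow(all_cells)))
    report$simulate <- list(n_brains = length(brains),
                            n_cells = nrow(all_cells))
  } else if (!is.null(config$cells_csv)) {
    tab <- load_cell_table(config$cells_csv)
    tab <- assign_regions(tab, config$brain_config$atlas)
    brains <- lapply(split(tab, tab$brain_id), function(df) {
      brain_dataset(df$brain_id[1], df, genotype = df$genotype[1])
    })
  }

  # --- serial detection + dedup -------------------------------------------
  if ("detect" %in% config$stages) {
    b1 <- brains[[1]]
    events <- simulate_serial_detections(b1, config$imaging,
                                         seed = mix_seed(config$seed, 101))
    write_events(events, file.path(out_dir, "events.csv"))
    corrected <- correct_axial_oversampling(events,
                                            radius = config$imaging$cell_radius_um)
    write_cells(cbind(corrected,
                      brain_id = b1$brain_id, genotype = b1$genotype,
                      class_label = "detected"),
                file.path(out_dir, "cells_corrected.csv"))
    report$detect <- list(n_true = nrow(b1$cells), n_events = nrow(events),
                          n_corrected = nrow(corrected))
    log_lines <- c(log_lines,
                   sprintf("detect: %d events -> %d corrected (true %d)",
                           nrow(events), nrow(corrected), nrow(b1$cells)))
  }

  # --- counts and NND ------------------------------------------------------
  classes <- names(config$brain_config$class_models)[1:2]
  if ("nnd" %in% config$stages) {
    nnd <- nnd_analysis(brains, classes = classes,
                        grid_size = config$grid_size)
    utils::write.csv(
      data.frame(grid = nnd$cdf$within_A$grid,
                 within_A = nnd$cdf$within_A$mean_cdf,
                 within_B = nnd$cdf$within_B$mean_cdf,
                 between = nnd$cdf$between$mean_cdf),
      file.path(out_dir, "nnd_cdf.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(A_vs_between = list(D = nnd$ks$A_vs_between$statistic,
                               p = nnd$ks$A_vs_between$p_value),
           B_vs_between = list(D = nnd$ks$B_vs_between$statistic,
                               p = nnd$ks$B_vs_between$p_value)),
      file.path(out_dir, "nnd_ks.json"), auto_unbox = TRUE, digits = NA)
    report$nnd <- nnd
    log_lines <- c(log_lines,
                   sprintf("nnd: KS D(A,between) = %.4f, D(B,between) = %.4f",
                           nnd$ks$A_vs_between$statistic,
                           nnd$ks$B_vs_between$statistic))
  }

  # --- clustering ----------------------------------------------------------
  if ("cluster" %in% config$stages) {
    point_sets <- lapply(brains, function(b) as_coord_matrix(b$cells))
    sel <- select_k_brains(point_sets, k_range = config$k_range,
                           seed = mix_seed(config$seed, 202),
                           n_init = config$n_init)
    comps <- lapply(seq_along(brains), function(i) {
      fit <- sel$per_brain[[i]]$fits[[paste0("k", sel$chosen_k)]]
      cluster_composition(fit$labels, brains[[i]]$cells$class_label)
    })
    caps <- capture_summary(comps)
    jsonlite::write_json(
      list(k_values = sel$k_values, silhouette_mean = sel$silhouette_mean,
           silhouette_sd = sel$silhouette_sd,
           silhouette_sem = sel$silhouette_sem,
           chosen_k = sel$chosen_k, capture = caps),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    report$cluster <- list(selection = sel, compositions = comps,
                           capture = caps)
    log_lines <- c(log_lines,
                   sprintf("cluster: chosen_k = %d, capture = %s",
                           sel$chosen_k,
                           paste(sprintf("%s %.3f", caps$class,
                                         caps$mean_capture),
                                 collapse = ", ")))
  }

  # --- orientation ---------------------------------------------------------
  if ("orient" %in% config$stages) {
    proc <- simulate_migration(config$migration,
                               seed = mix_seed(config$seed, 303))
    utils::write.csv(proc, file.path(out_dir, "processes.csv"),
                     row.names = FALSE, quote = FALSE)
    vec <- process_vectors(proc)
    frac <- dominant_axis_fractions(vec)
    hist2d <- angular_histogram(vec)
    md <- mean_direction(vec)
    jsonlite::write_json(
      list(axis_fractions = frac, mean_direction = md$direction,
           R_bar = md$R_bar),
      file.path(out_dir, "orientation.json"), auto_unbox = TRUE, digits = NA)
    report$orient <- list(fractions = frac, histogram = hist2d,
                          mean_direction = md)
    log_lines <- c(log_lines,
                   sprintf("orient: %d processes, R_bar = %.3f", nrow(proc),
                           md$R_bar))
  }

  # --- group statistics ----------------------------------------------------
  if ("stats" %in% config$stages) {
    counts <- lapply(brains, counts_by_region,
                     atlas = config$brain_config$atlas)
    pooled <- Reduce(`+`, counts)
    keep <- rowSums(pooled) > 0
    chi2 <- chi2_homogeneity(t(pooled[keep, , drop = FALSE]))
    report$stats <- list(chi2 = chi2, counts = pooled)
    jsonlite::write_json(
      list(chi2 = list(statistic = chi2$statistic, df = chi2$df,
                       p = chi2$p_value)),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
    log_lines <- c(log_lines,
                   sprintf("stats: chi2 = %.3f (df %d)", chi2$statistic,
                           chi2$df))
  }

  # --- bundle metadata -----------------------------------------------------
  resolved <- config
  resolved$brain_config$atlas <- NULL  # re-attached on read via demo_atlas
  jsonlite::write_json(
    list(seed = config$seed, n_brains = config$n_brains,
         stages = config$stages, k_range = config$k_range,
         n_init = config$n_init, grid_size = config$grid_size),
    file.path(out_dir, "config_resolved.json"), auto_unbox = TRUE,
    digits = NA)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(report)
}

#' Minimal command-line entry point
#'
#' `thalamap_main(c("run", "--seed", "7", "--out", "report"))` runs the full
#' synthetic pipeline; `"simulate"` writes only the synthetic inputs. Meant
#' for `Rscript -e 'thalamap::thalamap_main()'` style invocation.
#'
#' @param args character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
thalamap_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default) {
    i <- match(flag, args)
    if (is.na(i) || i == length(args)) default else args[i + 1L]
  }
  cmd <- if (length(args)) args[1L] else "help"
  seed <- as.integer(get_opt("--seed", "1"))
  out <- get_opt("--out", "thalamap_report")
  if (cmd == "run") {
    run_pipeline(pipeline_config(seed = seed), out)
    cat("report written to", out, "\n")
  } else if (cmd == "simulate") {
    run_pipeline(pipeline_config(seed = seed, stages = "simulate"), out)
    cat("synthetic cells written to", file.path(out, "cells.csv"), "\n")
  } else {
    cat("usage: thalamap_main(c('run'|'simulate', '--seed', <int>,",
        "'--out', <dir>))\n")
    return(invisible(1L))
  }
  invisible(0L)
}
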