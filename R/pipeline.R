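# End-to-end orchestration over the synthetic walkthrough: simulate ->
# normative fit -> W-scores -> ROI definition -> motion QC -> mixed model ->
# vertex-wise maps -> bootstrap precision, with a manifest recording seeds,
# configuration and per-stage outputs. A single global seed fans out to
# per-stage sub-seeds via a counter-based derivation, so omitting a stage
# does not perturb the draws of the others.

PIPELINE_STAGES <- c("simulate", "normative", "wscore", "roi", "qc",
                     "lme", "vertexwise", "precision")

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in order on a fully synthetic participant:
#' generates a vertex-level baseline map and a cluster-scan dataset, fits
#' the normative cohort model, converts the participant baseline to
#' W-scores, builds core and control ROIs, applies motion QC, fits the
#' mixed model (with the likelihood-ratio choice between nested and
#' scan-only random structures), produces vertex-wise change maps inside the
#' core mask, and computes bootstrap precision curves. All stochastic stages
#' are reproducible from `seed`: rerunning with the same seed rewrites
#' byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config An [analysis_config()].
#' @param stages Ordered subset of
#'   `c("simulate","normative","wscore","roi","qc","lme","vertexwise","precision")`.
#'   Later stages require the outputs of earlier ones within the same call.
#' @param seed Global integer seed (overrides `config$rng_seed`).
#' @param design Cluster-scan design `(timepoints, days, sessions, scans)`.
#' @param mesh_dim Grid-mesh dimensions for the synthetic cortex.
#' @param verbose Log stage progress to stderr.
#' @return The run manifest (named list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(out_dir, config = analysis_config(),
                         stages = PIPELINE_STAGES, seed = NULL,
                         design = c(3, 2, 2, 8), mesh_dim = c(12, 12),
                         verbose = TRUE) {
  cs_assert(all(stages %in% PIPELINE_STAGES),
            "unknown stage(s): %s", paste(setdiff(stages, PIPELINE_STAGES),
                                          collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  if (is.null(seed)) seed <- if (is.null(config$rng_seed)) 1L else config$rng_seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(seed = seed, config = unclass(config),
                   package_version = as.character(utils::packageVersion("clusterscan")),
                   stages = list())
  state <- new.env(parent = emptyenv())
  t_all <- Sys.time()

  record <- function(stage, outputs, t0) {
    manifest$stages[[stage]] <<- list(
      outputs = outputs,
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
  }
  path <- function(...) file.path(out_dir, ...)

  for (stage in stages) {
    t0 <- Sys.time()
    say("stage %s ...", stage)
    switch(stage,
      simulate = {
        s <- derive_seed(seed, 1)
        nr <- mesh_dim[1]; nc <- mesh_dim[2]
        parcels <- grid_parcels(nr, nc)
        mesh <- make_grid_mesh(nr, nc, parcel_of = parcels)
        nv <- mesh$n_vertices
        core_band <- which(parcels == "temporal")
        baseline <- rep(2.4, nv); baseline[core_band] <- 1.9
        decline <- rep(0.002, nv); decline[core_band] <- 0.02
        state$vtruth <- vertex_truth(baseline, decline, spatial_corr_steps = 1)
        state$truth <- synthetic_truth()
        state$mesh <- mesh
        state$vertex_data <- generate_vertex_dataset(
          state$vtruth, state$truth, mesh, design = design,
          noise_sd = 0.03, seed = s)
        sim <- generate_cluster_dataset(state$truth, design = design,
                                        seed = derive_seed(seed, 2))
        state$dataset <- sim$dataset
        write_scan_table(state$dataset, path("scan_table.csv"))
        write_mesh_tsv(mesh, path("mesh_edges.tsv"), path("mesh_parcels.tsv"))
        jsonlite::write_json(list(cell_means = state$truth$cell_means,
                                  sigma_day = state$truth$sigma_day,
                                  sigma_session = state$truth$sigma_session,
                                  sigma_scan = state$truth$sigma_scan,
                                  resid_sd = as.list(state$truth$resid_sd)),
                             path("truth.json"), auto_unbox = TRUE, digits = NA)
        record(stage, c("scan_table.csv", "mesh_edges.tsv", "mesh_parcels.tsv",
                        "truth.json"), t0)
      },
      normative = {
        state$cohort <- generate_normative_cohort(
          n_units = state$mesh$n_vertices, true_beta = c(3.05, -0.01, 0.05),
          resid_sd = 0.12, seed = derive_seed(seed, 3))
        state$normative <- fit_normative(state$cohort)
        write_normative_json(state$normative, path("normative_model.json"))
        record(stage, "normative_model.json", t0)
      },
      wscore = {
        # participant baseline: noise-free vertex map at the first timepoint
        baseline_map <- state$vtruth$baseline_map
        state$wmap <- compute_wscores(state$normative, age = 70, sex = 1,
                                      thickness = baseline_map)
        utils::write.table(
          data.frame(vertex = seq_along(state$wmap$w) - 1L, w = state$wmap$w),
          path("wscores.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
        record(stage, "wscores.tsv", t0)
      },
      roi = {
        state$core <- make_core_roi(state$wmap, state$mesh,
                                    threshold = config$w_core_threshold,
                                    min_size = 4)
        state$control <- make_control_roi(state$mesh, state$wmap,
                                          exclusion = config$w_control_exclusion)
        write_label_mask(state$core, path("core.label"),
                         values = state$wmap$w[state$core$vertices + 1L])
        write_label_mask(state$control, path("control.label"),
                         values = state$wmap$w[state$control$vertices + 1L])
        record(stage, c("core.label", "control.label"), t0)
      },
      qc = {
        qc <- filter_scans(state$dataset, threshold = config$motion_threshold)
        state$dataset <- qc$dataset
        utils::write.table(qc$report, path("qc_report.csv"), sep = ",",
                           row.names = FALSE, quote = FALSE)
        record(stage, "qc_report.csv", t0)
      },
      lme = {
        full <- fit_lme(state$dataset, random = "nested")
        simple <- fit_lme(state$dataset, random = "scan")
        lrt <- lrt_random_structure(full, simple, alpha = config$alpha)
        state$fit <- if (lrt$retain == "scan") simple else full
        state$emms <- estimated_marginal_means(state$fit, alpha = config$alpha)
        ctr <- pairwise_contrasts(state$fit, alpha = config$alpha)
        ictr <- interaction_contrasts(state$fit, alpha = config$alpha)
        ftab <- anova_fixed_effects(state$fit)
        ctr$percent_change <- vapply(seq_len(nrow(ctr)), function(i) {
          tp <- strsplit(ctr$label[i], " - ")[[1]]
          percent_change(state$emms, tp, roi = ctr$roi[i])
        }, numeric(1))
        utils::write.table(format_emm_table(state$emms), path("emm_table.csv"),
                           sep = ",", row.names = FALSE, quote = FALSE)
        utils::write.table(ctr, path("contrasts.csv"), sep = ",",
                           row.names = FALSE, quote = FALSE)
        utils::write.table(ictr, path("interaction_contrasts.csv"), sep = ",",
                           row.names = FALSE, quote = FALSE)
        utils::write.table(ftab, path("fixed_effects_tests.csv"), sep = ",",
                           row.names = FALSE, quote = FALSE)
        jsonlite::write_json(
          list(random = state$fit$random, lrt = lrt,
               varcomp = as.list(state$fit$varcomp), sigma2 = state$fit$sigma2,
               weights = as.list(state$fit$weights), logLik = state$fit$logLik,
               singular = state$fit$singular, df_method = state$fit$df_method),
          path("lme_fit.json"), auto_unbox = TRUE, digits = NA)
        record(stage, c("emm_table.csv", "contrasts.csv",
                        "interaction_contrasts.csv", "fixed_effects_tests.csv",
                        "lme_fit.json"), t0)
      },
      vertexwise = {
        vmap <- vertex_change_maps(state$vertex_data$thickness,
                                   state$vertex_data$scans,
                                   mask = state$core, alpha = config$alpha)
        utils::write.table(vmap, path("vertex_change_map.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        record(stage, "vertex_change_map.tsv", t0)
      },
      precision = {
        tps <- levels(state$dataset$records$timepoint)
        curves <- list()
        for (i in seq_along(tps[-1])) {
          lbl <- sprintf("%s - %s", tps[1], tps[i + 1])
          curve <- deviation_curve(
            scan_values(state$dataset, tps[1], "core"),
            scan_values(state$dataset, tps[i + 1], "core"),
            k_range = seq_len(config$max_scans), B = config$bootstrap_reps,
            seed = derive_seed(seed, 10 + i), label = lbl,
            rel_tol = config$plateau_rel_tol,
            consecutive = config$plateau_consecutive)
          curves[[lbl]] <- curve
          utils::write.table(as.data.frame(curve),
                             path(sprintf("precision_curve_%d.csv", i)),
                             sep = ",", row.names = FALSE, quote = FALSE)
        }
        plateau <- data.frame(
          interval = names(curves),
          reference_rate = vapply(curves, attr, numeric(1), "reference_rate"),
          plateau_k = vapply(curves, function(cv)
            as.integer(attr(cv, "plateau_k")), integer(1)),
          plateau_deviation = vapply(curves, attr, numeric(1),
                                     "plateau_deviation"))
        utils::write.table(plateau, path("plateau_summary.csv"), sep = ",",
                           row.names = FALSE, quote = FALSE)
        record(stage, c(sprintf("precision_curve_%d.csv",
                                seq_along(curves)), "plateau_summary.csv"), t0)
      })
  }
  manifest$total_seconds <- round(as.numeric(difftime(Sys.time(), t_all,
                                                      units = "secs")), 3)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# grid parcellation: a temporal-like band hosting the core atrophy plus
# pre/postcentral strips for the control ROI
grid_parcels <- function(nr, nc) {
  parcels <- matrix("other", nr, nc)
  pre_rows <- seq_len(max(1, floor(nr / 4)))
  post_rows <- pre_rows + length(pre_rows)
  parcels[pre_rows, ] <- "precentral"
  parcels[post_rows[post_rows <= nr], ] <- "postcentral"
  temporal_rows <- seq(floor(nr * 0.6) + 1, nr)
  parcels[temporal_rows, ] <- "temporal"
  as.vector(t(parcels))  # row-major to match 0-based vertex numbering
}

format_emm_table <- function(emms) {
  data.frame(timepoint = emms$timepoint,
             roi = if ("roi" %in% names(emms)) emms$roi else "unit",
             emm = round(emms$emm, 4), se = round(emms$se, 5),
             lower = round(emms$lower, 4), upper = round(emms$upper, 4))
}

#' Run the seeded demonstration pipeline
#'
#' Convenience wrapper over [run_pipeline()] with all stages and defaults.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (default 1).
#' @param ... Passed to [run_pipeline()].
#' @return The run manifest, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L, ...) {
  run_pipeline(out_dir, stages = PIPELINE_STAGES, seed = seed, ...)
}
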