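#' Run the analysis pipeline from a configuration
#'
#' Single entry point wiring the stages `simulate -> normalize -> icc -> di
#' -> eval -> robustness`. Each stage reads the artifacts of the previous
#' ones from `out_dir` (or the configured input paths), writes its outputs
#' as new files (inputs are never mutated), and drops a JSON provenance
#' sidecar per artifact (seed, thresholds, md5 of the inputs, package
#' version), so that every bootstrap result is reproducible bit-for-bit per
#' seed.
#'
#' The configuration is a named list or a YAML file with top-level keys
#' `seed`, `preset` (`"mouse"`: 10000 resamples, p < 0.005; `"human"`: 1000
#' resamples, p < 0.001), `stages`, `out_dir`, optional `inputs`
#' (`uptake`/`atlas`/`manifest` paths) and per-stage blocks; see the package
#' vignette for a worked configuration.
#'
#' @param config A named list or path to a YAML file.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a named list of produced artifact paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      msync_abort("config file not found: ", config, class = "microsync_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||% "microsync_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  preset <- config$preset %||% "mouse"
  defaults <- switch(preset,
    mouse = list(n_boot = 10000L, p_threshold = 0.005, z_threshold = 0.5),
    human = list(n_boot = 1000L, p_threshold = 0.001, z_threshold = 0.5),
    msync_abort("unknown preset: ", preset))
  n_boot <- as.integer(config$n_boot %||% defaults$n_boot)
  p_thr <- config$p_threshold %||% defaults$p_threshold
  z_thr <- config$z_threshold %||% defaults$z_threshold
  stages <- config$stages %||% c("simulate", "normalize", "icc", "di", "eval")
  artifacts <- list()

  path_of <- function(name) file.path(out_dir, name)
  sidecar <- function(artifact, inputs = character(), extra = list()) {
    prov <- c(list(
      artifact = basename(artifact),
      seed = seed, preset = preset, n_boot = n_boot,
      z_threshold = z_thr, p_threshold = p_thr,
      inputs = as.list(stats::setNames(
        unname(tools::md5sum(inputs[file.exists(inputs)])),
        basename(inputs[file.exists(inputs)]))),
      package_version = as.character(utils::packageVersion("microsync"))
    ), extra)
    jsonlite::write_json(prov, paste0(artifact, ".provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  run_stage <- function(name, fn) {
    msync_log("stage: ", name)
    tryCatch(fn(), error = function(e) {
      msync_abort("stage '", name, "' failed: ", conditionMessage(e),
                  class = "microsync_stage_error")
    })
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sim <- config$simulate %||% list()
      atlas <- synthetic_mouse_atlas()
      healthy <- synthetic_config(
        atlas = atlas,
        n_subjects = sim$n_subjects %||% 14,
        seed = seed)
      stage_drops <- sim$desync_loading_drops %||% c(0.3, 0.6)
      stage_infl <- sim$desync_noise_inflations %||% c(1.5, 2.5)
      desync_regions <- sim$desync_regions %||%
        atlas$voi_id[atlas$compartment == "cortical"]
      disease <- Map(function(drop, infl) {
        synthetic_config(atlas = atlas, n_subjects = sim$n_subjects %||% 14,
                         desync_regions = desync_regions,
                         desync_loading_drop = drop,
                         desync_noise_inflation = infl, seed = seed)
      }, stage_drops, stage_infl)
      study <- generate_study(healthy, disease)
      write_uptake_table(study$uptake, path_of("uptake.csv"))
      write_atlas(study$atlas, path_of("atlas.csv"))
      write_manifest(study$manifest, path_of("manifest.csv"))
      sidecar(path_of("uptake.csv"))
      artifacts$uptake <<- path_of("uptake.csv")
      artifacts$atlas <<- path_of("atlas.csv")
      artifacts$manifest <<- path_of("manifest.csv")
    })
  }

  inputs <- config$inputs %||% list()
  uptake_path <- artifacts$uptake %||% inputs$uptake
  atlas_path <- artifacts$atlas %||% inputs$atlas
  manifest_path <- artifacts$manifest %||% inputs$manifest
  for (nm in c("uptake", "atlas", "manifest")) {
    p <- get(paste0(nm, "_path"))
    if (is.null(p) || !file.exists(p)) {
      msync_abort("required ", nm, " input missing or not found: ",
                  p %||% "(unset)", class = "microsync_io_error")
    }
  }
  uptake <- read_uptake_table(uptake_path)
  atlas <- read_atlas(atlas_path)
  manifest <- read_manifest(manifest_path)
  cohorts <- unique(manifest$cohort)

  if ("normalize" %in% stages) {
    run_stage("normalize", function() {
      suvr <- global_mean_scale(uptake)
      write_uptake_table(suvr, path_of("suvr.csv"))
      sidecar(path_of("suvr.csv"), uptake_path)
      artifacts$suvr <<- path_of("suvr.csv")
    })
  }
  suvr <- if (file.exists(path_of("suvr.csv"))) {
    read_uptake_table(path_of("suvr.csv"), normalization = "global_mean")
  } else {
    global_mean_scale(uptake)
  }

  if ("icc" %in% stages) {
    run_stage("icc", function() {
      icc_cohorts <- config$icc$cohorts %||% cohorts
      summaries <- list()
      conn <- list()
      for (co in icc_cohorts) {
        tab <- cohort_table(suvr, manifest, co)
        icc <- compute_icc_matrix(tab, n_rep = n_boot, seed = seed)
        utils::write.csv(icc$z_mean, path_of(sprintf("icc_matrix_%s.csv", co)))
        utils::write.csv(icc$p_values, path_of(sprintf("icc_pvalues_%s.csv", co)))
        cs <- significant_connections(icc, atlas, z_thr, p_thr)
        utils::write.csv(cs$edges, path_of(sprintf("connections_%s.csv", co)),
                         row.names = FALSE)
        summaries[[co]] <- c(median_abs_icc(icc),
                             list(total_connections = cs$total,
                                  class_counts = as.list(cs$class_counts)))
        conn[[co]] <- cs$total
      }
      for (co in icc_cohorts) {
        ref <- manifest$reference_cohort[manifest$cohort == co][1]
        if (!is.na(ref) && ref %in% names(conn) && conn[[ref]] > 0) {
          summaries[[co]]$connection_ratio <-
            round(connection_ratio(conn[[co]], conn[[ref]]), 2)
        }
      }
      jsonlite::write_json(summaries, path_of("icc_summary.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      sidecar(path_of("icc_summary.json"), c(uptake_path, atlas_path))
      artifacts$icc_summary <<- path_of("icc_summary.json")
    })
  }

  if ("di" %in% stages) {
    run_stage("di", function() {
      train_cohort <- config$di$train_cohort %||% "CTRL_train"
      vois <- config$di$vois %||% suvr$vois
      train <- cohort_table(suvr, manifest, train_cohort)
      model <- fit_pair_models(train, voi_subset = vois, n_rep = n_boot,
                               seed = seed)
      fits <- icc_model_as_df(model)
      utils::write.csv(fits, path_of("pairfits.csv"), row.names = FALSE)
      others <- setdiff(cohorts, train_cohort)
      scored <- lapply(others, function(co) {
        score_subjects(cohort_table(suvr, manifest, co), model)
      })
      loo <- loo_reference_di(train, voi_subset = vois, n_rep = n_boot,
                              seed = seed)
      di <- do.call(rbind_di, c(scored, list(loo)))
      df <- data.frame(subject_id = di$subjects, di$values,
                       check.names = FALSE)
      utils::write.csv(df, path_of("di_table.csv"), row.names = FALSE)
      sidecar(path_of("di_table.csv"), c(uptake_path, manifest_path))
      artifacts$di_table <<- path_of("di_table.csv")
    })
  }

  if ("eval" %in% stages && file.exists(path_of("di_table.csv"))) {
    run_stage("eval", function() {
      df <- utils::read.csv(path_of("di_table.csv"), check.names = FALSE)
      vals <- as.matrix(df[, -1, drop = FALSE])
      rownames(vals) <- df$subject_id
      di <- di_table(vals)
      groups <- config$eval$groups %||% utils::tail(cohorts, 3)
      gs <- di_group_stats(di, manifest, groups)
      utils::write.csv(gs, path_of("group_stats.csv"), row.names = FALSE)
      sig <- gs$voi_id[gs$significant %in% TRUE]
      if (length(sig) >= 2) {
        pc <- pc1_of_di(di, sig)
        utils::write.csv(data.frame(subject_id = names(pc$scores),
                                    pc1 = unname(pc$scores)),
                         path_of("pc1.csv"), row.names = FALSE)
      }
      if ("cognition" %in% names(manifest)) {
        scores <- stats::setNames(manifest$cognition, manifest$subject_id)
        cg <- correlate_di_cognition(di, scores)
        utils::write.csv(cg, path_of("cognition_corr.csv"), row.names = FALSE)
      }
      sidecar(path_of("group_stats.csv"), path_of("di_table.csv"))
      artifacts$group_stats <<- path_of("group_stats.csv")
    })
  }

  if ("robustness" %in% stages) {
    run_stage("robustness", function() {
      rb <- config$robustness %||% list()
      ca <- cohort_table(suvr, manifest, rb$cohort_a %||% cohorts[1])
      cb <- cohort_table(suvr, manifest, rb$cohort_b %||% cohorts[2])
      curve <- subject_drop_curve(ca, cb,
                                  min_n = rb$min_n %||% 6,
                                  n_draws = rb$n_draws %||% 20,
                                  n_boot = rb$n_boot %||% n_boot,
                                  seed = seed)
      utils::write.csv(attr(curve, "summary"), path_of("robustness_curve.csv"),
                       row.names = FALSE)
      sidecar(path_of("robustness_curve.csv"), uptake_path)
      artifacts$robustness <<- path_of("robustness_curve.csv")
    })
  }

  invisible(artifacts)
}

# Flatten a pairwise_fit_model into a (voi_i, voi_j, slope, intercept) table.
icc_model_as_df <- function(model) {
  p <- length(model$vois)
  ut <- which(upper.tri(model$slope), arr.ind = TRUE)
  data.frame(voi_i = model$vois[ut[, 1]],
             voi_j = model$vois[ut[, 2]],
             slope = model$slope[ut],
             intercept = model$intercept[ut],
             n_rep = model$n_rep,
             stringsAsFactors = FALSE)
}
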