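#' Synthetic mouse-style atlas
#'
#' A 21-region atlas with the structure of a rodent region-mean set used for
#' whole-brain tracer extraction: five bilateral cortical subdivisions, four
#' bilateral subcortical nuclei, and three midline regions; compartments are
#' `cortical` / `subcortical`. All region names are synthetic stand-ins.
#'
#' @return An [atlas_metadata()] with 21 VOIs (9 bilateral pairs).
#' @export
synthetic_mouse_atlas <- function() {
  bilat_ctx <- c("visual_ctx", "auditory_ctx", "entorhinal_ctx",
                 "sensorimotor_ctx", "somatosensory_ctx")
  bilat_sub <- c("amygdala", "hippocampus", "striatum", "thalamus")
  voi <- c(paste0(rep(bilat_ctx, each = 2), c("_l", "_r")),
           "frontal_ctx",
           paste0(rep(bilat_sub, each = 2), c("_l", "_r")),
           "cerebellum", "brainstem")
  comp <- c(rep("cortical", 11), rep("subcortical", 10))
  hemi <- c(rep(c("L", "R"), 5), "bilateral", rep(c("L", "R"), 4),
            "bilateral", "bilateral")
  atlas_metadata(voi, comp, hemi)
}

#' Synthetic human-style atlas
#'
#' Parcellation-style region lists for the disease-signature network
#' (parietal + temporal VOIs) and the motor-sensory control network. Region
#' names are synthetic stand-ins for a cortical parcellation.
#'
#' @param n_parietal,n_temporal,n_motor_sensory Region counts per
#'   compartment (defaults mirror a 94-VOI signature network plus 27
#'   motor-sensory control VOIs).
#' @return An [atlas_metadata()].
#' @export
synthetic_human_atlas <- function(n_parietal = 50, n_temporal = 44,
                                  n_motor_sensory = 27) {
  mk <- function(prefix, n) {
    side <- rep(c("L", "R"), length.out = n)
    sprintf("%s_%s_%02d", prefix, tolower(side), seq_len(n))
  }
  voi <- c(mk("parietal", n_parietal), mk("temporal", n_temporal),
           mk("motor_sensory", n_motor_sensory))
  comp <- c(rep("parietal", n_parietal), rep("temporal", n_temporal),
            rep("motor_sensory", n_motor_sensory))
  hemi <- ifelse(grepl("_l_", voi), "L", "R")
  atlas_metadata(voi, comp, hemi)
}

#' Synthetic cohort configuration
#'
#' Describes one cohort of the generative model behind all synthetic data:
#' per subject `s` a standard-normal shared activation factor `f_s` and a
#' log-normal global scale `g_s` (injected-activity variability); per region
#' `r` the uptake is
#' `g_s * max(eps, baseline_r + loading_r * f_s + N(0, sd_r))`.
#' The shared factor induces the high interregional correlation of healthy
#' cohorts. Desynchronization is region-restricted: within `desync_regions`
#' the loading is multiplied by `1 - desync_loading_drop` and the noise SD
#' by `desync_noise_inflation`, both modulated per subject by a log-normal
#' severity draw. The subject's latent desynchronization magnitude couples
#' linearly (negatively) to the generated cognition score.
#'
#' @param atlas An [atlas_metadata()] defining the VOI set.
#' @param n_subjects Cohort size.
#' @param baseline_mean Per-VOI positive baseline uptake; default 1.1 for
#'   cortical-type regions and 0.95 otherwise (SUVR-like scale).
#' @param shared_factor_loading Per-VOI loading on the shared factor.
#'   The default is a fixed ramp from -0.08 to 0.32 over the region list
#'   (mean 0.12, about 2x the regional noise SD). The regional heterogeneity
#'   is essential: a perfectly uniform loading would be cancelled by global
#'   mean scaling, whereas a regionally structured activation pattern
#'   survives it and yields the dense connectome of a synchronized cohort
#'   (including negatively correlated region pairs).
#' @param region_noise_sd Per-VOI residual SD (default 0.06).
#' @param desync_regions VOI ids with desynchronization (default none).
#' @param desync_loading_drop Loading reduction in `[0, 1]` inside
#'   `desync_regions`.
#' @param desync_noise_inflation Noise SD multiplier >= 1 inside
#'   `desync_regions`.
#' @param severity_sd SD of the log-normal per-subject severity modulation.
#' @param global_scale_sd SD of `log(g_s)` (default 0.2, about 20%
#'   injected-activity variability).
#' @param cognition_base,cognition_slope,cognition_noise_sd Cognition score
#'   model `score = base - slope * latent + N(0, noise)`; defaults emulate
#'   an MMSE-like score (ceiling 29, strong coupling, 1.5-point noise).
#' @param seed Integer seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(atlas = synthetic_mouse_atlas(),
                             n_subjects = 14,
                             baseline_mean = NULL,
                             shared_factor_loading = NULL,
                             region_noise_sd = 0.06,
                             desync_regions = character(0),
                             desync_loading_drop = 0,
                             desync_noise_inflation = 1,
                             severity_sd = 0.25,
                             global_scale_sd = 0.2,
                             cognition_base = 29,
                             cognition_slope = 6,
                             cognition_noise_sd = 1.5,
                             seed = 1L) {
  vois <- atlas$voi_id
  p <- length(vois)
  baseline_mean <- baseline_mean %||%
    ifelse(grepl("ctx|parietal|temporal|motor", vois), 1.1, 0.95)
  baseline_mean <- stats::setNames(rep_len(baseline_mean, p), vois)
  shared_factor_loading <- shared_factor_loading %||%
    seq(-0.08, 0.32, length.out = p)
  shared_factor_loading <- stats::setNames(rep_len(shared_factor_loading, p), vois)
  region_noise_sd <- stats::setNames(rep_len(region_noise_sd, p), vois)
  if (n_subjects < 3) {
    msync_abort("n_subjects must be >= 3", class = "microsync_validation_error")
  }
  if (any(baseline_mean <= 0) || any(region_noise_sd < 0) ||
      global_scale_sd < 0 || severity_sd < 0 || cognition_noise_sd < 0) {
    msync_abort("means must be positive and SDs non-negative",
                class = "microsync_validation_error")
  }
  if (desync_loading_drop < 0 || desync_loading_drop > 1 ||
      desync_noise_inflation < 1) {
    msync_abort("desync_loading_drop must be in [0,1], desync_noise_inflation >= 1",
                class = "microsync_validation_error")
  }
  if (!all(desync_regions %in% vois)) {
    msync_abort("desync_regions must be a subset of the atlas VOIs",
                class = "microsync_validation_error")
  }
  structure(
    list(atlas = atlas, voi_ids = vois, n_subjects = as.integer(n_subjects),
         baseline_mean = baseline_mean,
         shared_factor_loading = shared_factor_loading,
         region_noise_sd = region_noise_sd,
         desync_regions = desync_regions,
         desync_loading_drop = desync_loading_drop,
         desync_noise_inflation = desync_noise_inflation,
         severity_sd = severity_sd,
         global_scale_sd = global_scale_sd,
         cognition_base = cognition_base,
         cognition_slope = cognition_slope,
         cognition_noise_sd = cognition_noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate one synthetic cohort
#'
#' Draws a cohort from the model described in [synthetic_config()]. The
#' manifest carries the generated cognition score and the latent
#' desynchronization magnitude of each subject (the ground truth against
#' which recovery is tested; cognition is coupled to the latent, not to the
#' measured index, to keep recovery tests non-circular).
#'
#' @param cfg A [synthetic_config()].
#' @param label Cohort label for the manifest.
#' @param reference_label Reference-cohort label (`NA` = scored by
#'   leave-one-out).
#' @return A list: `uptake` (raw [uptake_table()]), `manifest`
#'   ([cohort_manifest()] with covariates `cognition` and `latent_desync`).
#' @export
generate_cohort <- function(cfg, label = "COHORT", reference_label = NA_character_) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_subjects
  p <- length(cfg$voi_ids)
  eps <- 1e-6
  with_seed(cfg$seed, {
    # all randomness drawn as unit normals and scaled afterwards, so that
    # changing an SD parameter never shifts the RNG stream of the others
    f <- stats::rnorm(n)
    g <- exp(cfg$global_scale_sd * stats::rnorm(n))
    sev <- exp(cfg$severity_sd * stats::rnorm(n))
    noise <- matrix(stats::rnorm(n * p), n, p)
    cog_noise <- cfg$cognition_noise_sd * stats::rnorm(n)
    is_desync <- cfg$voi_ids %in% cfg$desync_regions
    drop_s <- pmin(1, cfg$desync_loading_drop * sev)
    infl_s <- 1 + (cfg$desync_noise_inflation - 1) * sev
    latent <- drop_s + (infl_s - 1)        # latent desynchronization magnitude
    L <- matrix(cfg$shared_factor_loading, n, p, byrow = TRUE)
    S <- matrix(cfg$region_noise_sd, n, p, byrow = TRUE)
    L[, is_desync] <- L[, is_desync] * (1 - drop_s)
    S[, is_desync] <- S[, is_desync] * infl_s
    base <- matrix(cfg$baseline_mean, n, p, byrow = TRUE)
    vals <- g * pmax(base + L * f + S * noise, eps)
    rownames(vals) <- sprintf("%s_%02d", label, seq_len(n))
    colnames(vals) <- cfg$voi_ids
    cognition <- cfg$cognition_base - cfg$cognition_slope * latent + cog_noise
    manifest <- cohort_manifest(
      subject_id = rownames(vals), cohort = label,
      reference_cohort = reference_label,
      cognition = cognition, latent_desync = latent)
    list(uptake = uptake_table(vals, normalization = "raw"),
         manifest = manifest)
  })
}

#' Generate a multi-cohort synthetic study
#'
#' Emits a study bundle mirroring the reference design: a healthy training
#' cohort (`CTRL_train`, the normative reference), a healthy test cohort
#' (`CTRL_test`, drawn from the same configuration with an offset seed), and
#' one cohort per disease configuration (typically staged with increasing
#' desynchronization). All cohorts share the healthy configuration's VOI
#' set; non-training cohorts reference `CTRL_train`.
#'
#' @param healthy_cfg A [synthetic_config()] without desynchronization.
#' @param disease_cfgs List of [synthetic_config()]s over the same VOI set.
#' @param disease_labels Cohort labels (default `DISEASE_1`, ...).
#' @return A list: `uptake` (combined raw [uptake_table()]), `manifest`
#'   (combined), `atlas`, `cohorts` (character vector of labels; length =
#'   number of configurations + 1).
#' @export
generate_study <- function(healthy_cfg, disease_cfgs = list(),
                           disease_labels = NULL) {
  stopifnot(inherits(healthy_cfg, "synthetic_config"))
  for (cfg in disease_cfgs) {
    if (!identical(cfg$voi_ids, healthy_cfg$voi_ids)) {
      msync_abort("all configurations must share the healthy VOI set",
                  class = "microsync_validation_error")
    }
  }
  disease_labels <- disease_labels %||%
    sprintf("DISEASE_%d", seq_along(disease_cfgs))
  stopifnot(length(disease_labels) == length(disease_cfgs))
  train_cfg <- healthy_cfg
  test_cfg <- healthy_cfg
  test_cfg$seed <- healthy_cfg$seed + 1L
  parts <- list(generate_cohort(train_cfg, "CTRL_train", NA_character_),
                generate_cohort(test_cfg, "CTRL_test", "CTRL_train"))
  for (i in seq_along(disease_cfgs)) {
    cfg <- disease_cfgs[[i]]
    cfg$seed <- cfg$seed + 1L + i   # keep cohort streams distinct by default
    parts[[2 + i]] <- generate_cohort(cfg, disease_labels[i], "CTRL_train")
  }
  vals <- do.call(rbind, lapply(parts, function(x) x$uptake$values))
  manifest <- do.call(rbind, lapply(parts, `[[`, "manifest"))
  class(manifest) <- c("cohort_manifest", "data.frame")
  list(uptake = uptake_table(vals, normalization = "raw"),
       manifest = manifest,
       atlas = healthy_cfg$atlas,
       cohorts = c("CTRL_train", "CTRL_test", disease_labels))
}
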