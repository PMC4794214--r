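#' Configuration for an end-to-end analysis run
#'
#' Defaults correspond to the full-scale analysis (500,000 patches of 25 x
#' 25 pixels, 200 subspaces of two subunits, 100 phase steps, DDI
#' threshold 0.6); scale `n_patches`, `n_subspaces` and the image counts
#' down for desk-scale runs.
#'
#' @param source `"synthetic"` (generate stereo pairs) or `"directory"`
#'   (read `_L`/`_R` image pairs from `image_dir`).
#' @param image_dir Directory of stereo images when `source="directory"`.
#' @param n_pairs,width,height Synthetic image set geometry.
#' @param field A [disparity_field_spec()] for the synthetic scenes.
#' @param spectral_slope Amplitude-spectrum slope of the synthetic scenes.
#' @param n_patches,patch_px Patch sample size and side length.
#' @param whitening_k Retained whitened dimensions; defaults to
#'   `n_subspaces * subunits_per_subspace` so the learned component matrix
#'   is square and orthonormal in whitened space.
#' @param n_subspaces,subunits_per_subspace ISA layout.
#' @param isa An [isa_options()]; its seed is overridden by the per-stage
#'   seed derived from `seed`.
#' @param probe_method `"gabor"` (Gabor-fit means) or `"search"`
#'   (response-maximizing grid search).
#' @param n_phase_steps Phase samples per axis of the phase-phase maps.
#' @param bar_maps Whether to also compute bar shift-shift maps.
#' @param bar_range,bar_steps Bar shift grid.
#' @param rules Pooling rules to evaluate.
#' @param ddi_threshold DDI cutoff for symmetry classification.
#' @param n_boot Bootstrap resamples for population summaries.
#' @param gabor_restarts Restarts per Gabor fit.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(source = c("synthetic", "directory"),
                       image_dir = NULL,
                       n_pairs = 20, width = 512, height = 512,
                       field = disparity_field_spec(),
                       spectral_slope = -1,
                       n_patches = 500000, patch_px = 25,
                       whitening_k = NULL,
                       n_subspaces = 200, subunits_per_subspace = 2,
                       isa = isa_options(),
                       probe_method = c("gabor", "search"),
                       n_phase_steps = 100,
                       bar_maps = FALSE, bar_range = 12.5, bar_steps = 51,
                       rules = c("energy", "maxpool"),
                       ddi_threshold = 0.6, n_boot = 200,
                       gabor_restarts = 3, seed = 1L) {
  source <- match.arg(source)
  probe_method <- match.arg(probe_method)
  rules <- match.arg(rules, several.ok = TRUE)
  if (is.null(whitening_k))
    whitening_k <- n_subspaces * subunits_per_subspace
  cfg <- list(source = source, image_dir = image_dir, n_pairs = n_pairs,
              width = width, height = height, field = field,
              spectral_slope = spectral_slope, n_patches = n_patches,
              patch_px = patch_px, whitening_k = whitening_k,
              n_subspaces = n_subspaces,
              subunits_per_subspace = subunits_per_subspace, isa = isa,
              probe_method = probe_method, n_phase_steps = n_phase_steps,
              bar_maps = bar_maps, bar_range = bar_range,
              bar_steps = bar_steps, rules = rules,
              ddi_threshold = ddi_threshold, n_boot = n_boot,
              gabor_restarts = gabor_restarts, seed = as.integer(seed))
  counts <- c(n_pairs, width, height, n_patches, patch_px, whitening_k,
              n_subspaces, subunits_per_subspace, n_phase_steps, n_boot)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("all counts in the configuration must be positive")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `field` and
#' `isa` may be nested mappings with the arguments of
#' [disparity_field_spec()] and [isa_options()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$field)) y$field <- do.call(disparity_field_spec, y$field)
  if (!is.null(y$isa)) y$isa <- do.call(isa_options, y$isa)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the stages image generation/ingest -> patch sampling and
#' preprocessing -> whitening and ISA -> probe parameters -> response maps
#' -> disparity metrics, persisting each stage's output in `outdir` so a
#' rerun resumes from the last completed stage (delete a stage file to
#' recompute it and everything downstream of it).  All randomness is
#' driven by per-stage seeds derived deterministically from the master
#' seed, so identical configurations yield identical outputs.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return A list with `characterizations` (per rule, one entry per
#'   usable subspace), `summaries` (per rule, from
#'   [population_summary()]), `isa` (the fitted model), `excluded`
#'   (subspaces without usable probe parameters) and `outdir`.  A
#'   characterization table (`characterizations.csv`) and a summary
#'   (`summary.json`) are also written to `outdir`.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, compute) {
    f <- file.path(outdir, paste0(name, ".rds"))
    if (file.exists(f)) {
      say("stage %s: reusing %s", name, f)
      return(readRDS(f))
    }
    say("stage %s: computing", name)
    out <- compute()
    saveRDS(out, f)
    out
  }
  seed_of <- function(name) stage_seed(config$seed, name)

  images <- stage("01_images", function() {
    if (config$source == "directory") {
      pairs <- read_stereo_dir(config$image_dir)
    } else {
      s0 <- seed_of("images")
      pairs <- lapply(seq_len(config$n_pairs), function(i) {
        fld <- config$field
        fld$seed <- as.integer((s0 + 7919 * i) %% 2147483629)
        generate_stereo_pair(config$width, config$height, fld,
                             spectral_slope = config$spectral_slope,
                             seed = as.integer((s0 + i) %% 2147483629))
      })
    }
    pairs
  })

  prep <- stage("02_patches", function() {
    raw <- sample_patches(images, config$n_patches, config$patch_px,
                          seed = seed_of("patches"))
    preprocess_patches(raw)
  })

  isa <- stage("03_isa", function() {
    wt <- fit_whitening(prep, config$whitening_k)
    Z <- apply_whitening(wt, prep)
    opts <- config$isa
    opts$seed <- seed_of("isa")
    fit_isa(Z, config$n_subspaces, config$subunits_per_subspace,
            opts = opts, whitening = wt)
  })

  probes <- stage("04_probes", function() {
    models <- subspace_models(isa, rule = "energy")
    lapply(models, function(m) {
      if (config$probe_method == "search") {
        probe_params_by_search(m)
      } else {
        model_probe_params(m, fit_model_gabors(m, config$gabor_restarts))
      }
    })
  })

  maps <- stage("05_maps", function() {
    out <- list()
    for (rule in config$rules) {
      models <- subspace_models(isa, rule = rule)
      out[[rule]] <- lapply(seq_along(models), function(s) {
        if (is.null(probes[[s]])) return(NULL)
        pm <- phase_phase_map(models[[s]], probes[[s]],
                              n_steps = config$n_phase_steps)
        bm <- if (config$bar_maps)
          bar_shift_map(models[[s]], probes[[s]], -config$bar_range,
                        config$bar_range, config$bar_steps)
        list(phase = pm, bar = bm)
      })
    }
    out
  })

  metrics <- stage("06_metrics", function() {
    chars <- list()
    summaries <- list()
    for (rule in config$rules) {
      ch <- lapply(seq_along(maps[[rule]]), function(s) {
        mp <- maps[[rule]][[s]]
        if (is.null(mp)) return(NULL)
        tuning <- disparity_tuning(mp$phase)
        fit <- fit_sine(tuning)
        ddi <- compute_ddi(tuning, fit)
        sym <- classify_symmetry(fit, ddi, config$ddi_threshold)
        structure(list(model_id = s, rule = rule, probe = probes[[s]],
                       ddi = ddi, sine = fit, symmetry = sym$label,
                       response_phase = sym$response_phase),
                  class = "disparity_characterization")
      })
      chars[[rule]] <- Filter(Negate(is.null), ch)
      summaries[[rule]] <- population_summary(
        chars[[rule]], ddi_threshold = config$ddi_threshold,
        n_boot = config$n_boot, seed = seed_of(paste0("boot_", rule)))
    }
    list(characterizations = chars, summaries = summaries)
  })

  excluded <- which(vapply(probes, is.null, TRUE))
  say("excluded %d of %d subspaces (no usable probe parameters)",
      length(excluded), config$n_subspaces)

  write_characterization_csv(metrics$characterizations,
                             file.path(outdir, "characterizations.csv"))
  write_summary_json(metrics$summaries, config,
                     file.path(outdir, "summary.json"))

  list(characterizations = metrics$characterizations,
       summaries = metrics$summaries, isa = isa,
       excluded = excluded, outdir = outdir)
}

write_characterization_csv <- function(chars_by_rule, path) {
  rows <- list()
  for (rule in names(chars_by_rule)) {
    for (ch in chars_by_rule[[rule]]) {
      rows[[length(rows) + 1]] <- data.frame(
        model_id = ch$model_id, rule = rule,
        probe_frequency = ch$probe$frequency,
        probe_orientation = ch$probe$orientation,
        ddi = ch$ddi, sine_amplitude = ch$sine$amplitude,
        sine_phase = ch$sine$phase, sine_offset = ch$sine$offset,
        response_phase = ch$response_phase, symmetry = ch$symmetry)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

write_summary_json <- function(summaries, config, path) {
  out <- lapply(summaries, function(s) list(
    n = s$n,
    frac_above_threshold = s$frac_above_threshold,
    ddi_p95 = round(s$ddi_p95, 10),
    ddi_max = round(s$ddi_max, 10),
    labels = as.list(s$labels),
    label_proportions = s$label_proportions))
  out$config <- list(n_patches = config$n_patches,
                     patch_px = config$patch_px,
                     n_subspaces = config$n_subspaces,
                     subunits_per_subspace = config$subunits_per_subspace,
                     ddi_threshold = config$ddi_threshold,
                     seed = config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
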