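#' Run the full quantification pipeline on one synthetic embryo
#'
#' Generates a synthetic embryo for a genotype preset and runs every
#' analysis stage on the rendered data: closure kinetics on the hole series,
#' AS pulsation/shape/area on the rasterized cell-sheet movie (via label
#' extraction, tracking and central-cell selection), and filopodia metrics
#' on the simulated annotations.  Optionally writes all results (CSV/JSON)
#' and a run log to `out_dir`.
#'
#' @param preset Genotype name (see [make_preset()]) or an `embryo_preset`.
#' @param seed Integer seed used for every stochastic stage.
#' @param noise Render with measurement noise?
#' @param k Number of central AS cells analyzed.
#' @param prominence Pulse-prominence threshold.
#' @param gap_width Gap width (um) starting the AS window.
#' @param out_dir Optional output directory.
#' @return A `dc_run` object: list with `preset`, `hole`, `kinetics`
#'   ([kinetic_summary()]), `pulsation` (see [quantify_pulsation()]),
#'   `filopodia` ([filopodia_stats()] result plus truth), and `seed`.
#' @export
run_quantify <- function(preset, seed = 1L, noise = FALSE, k = 6L,
                         prominence = 0.02, gap_width = 50, out_dir = NULL) {
  if (is.character(preset)) preset <- make_preset(preset)
  validate_preset(preset)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for preset '", preset$name, "': ",
           conditionMessage(e), call. = FALSE))
  }
  hole <- stage("simulate_closure", simulate_closure(preset, seed, noise))
  kin <- stage("closure_kinetics", kinetic_summary(hole))
  sheet <- stage("simulate_as_sheet", simulate_as_sheet(preset, seed, noise))
  puls <- stage("as_dynamics",
                quantify_pulsation(sheet$movie, k = k,
                                   prominence = prominence))
  filo_sim <- stage("simulate_filopodia", simulate_filopodia(preset, seed))
  filo <- stage("filopodia_metrics", filopodia_stats(filo_sim$stripes))
  out <- list(preset = preset, seed = seed, noise = noise, hole = hole,
              kinetics = kin, pulsation = puls,
              filopodia = c(filo, list(truth = filo_sim$truth)),
              sheet_truth = sheet$truth)
  class(out) <- "dc_run"
  if (!is.null(out_dir)) .write_run(out, out_dir)
  out
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- run$preset
  utils::write.csv(
    data.frame(t = run$hole$t, W = run$hole$W, L = run$hole$L),
    file.path(out_dir, "hole_series.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(t = run$kinetics$t, v_conv = run$kinetics$v_conv,
               v_zip = run$kinetics$v_zip),
    file.path(out_dir, "speed_curves.csv"), row.names = FALSE)
  s <- run$pulsation$summary
  s$genotype <- p$name
  utils::write.csv(s, file.path(out_dir, "as_cells.csv"), row.names = FALSE)
  k <- run$kinetics
  jsonlite::write_json(
    list(genotype = p$name, seed = run$seed, noise = run$noise,
         W0 = p$W0, L0 = p$L0,
         duration = k$duration, max_conv = k$max_conv, conv_t0 = k$conv_t0,
         zip_t0 = k$zip_t0, mean_zip_0_84 = k$mean_zip_0_84,
         max_zip_first_phase = k$max_zip_first_phase,
         lw_ratio_at_30 = k$lw_ratio_at_30,
         filopodia_mean_count = run$filopodia$mean_count,
         filopodia_mean_length = run$filopodia$mean_length),
    file.path(out_dir, "kinetics.json"), auto_unbox = TRUE, digits = NA)
  write_preset_yaml(p, file.path(out_dir, "preset.yaml"))
  invisible(out_dir)
}

#' @export
print.dc_run <- function(x, ...) {
  cat("Quantification run for preset '", x$preset$name, "' (seed ", x$seed,
      if (x$noise) ", with noise" else ", noise-free", ")\n", sep = "")
  print(x$kinetics)
  cat(sprintf("  AS pulsation: mean amplitude %.4f, mean count %.2f (over %d cells)\n",
              mean(x$pulsation$summary$amplitude),
              mean(x$pulsation$summary$count),
              nrow(x$pulsation$summary)))
  cat(sprintf("  filopodia: mean count/stripe %.2f, mean length %.2f um\n",
              x$filopodia$mean_count, x$filopodia$mean_length))
  invisible(x)
}

#' Parameter-recovery benchmark over genotype presets
#'
#' Renders noise-free movies for the requested presets, reruns the full
#' analysis pipeline, and tabulates generated-truth vs recovered values for
#' every kinetic anchor the presets encode: closure duration, initial and
#' maximal LE convergence speed, zipping speed at timepoint zero, mean
#' zipping speed over the first 84 min, first-phase maximum zipping speed,
#' and (for mutants) the relative reduction of AS pulse amplitude vs the
#' control preset.  Expected values are derived from the preset knot tables
#' themselves, so a corrupted preset fails its targets.
#'
#' @param presets Character vector of preset names (the control preset must
#'   be included for amplitude-reduction rows, and is added if missing).
#' @param seed Integer seed.
#' @param tol_speed Absolute tolerance for speed recovery (um/min).
#' @param reduction_min Lower bound (%) on mutant pulse-amplitude reduction.
#' @return A data.frame with `metric`, `genotype`, `expected`, `recovered`,
#'   `tol`, `pass` (empty when `presets` is empty).
#' @export
run_benchmark <- function(presets = c("WT", "DAAM", "frl", "form3", "dia"),
                          seed = 1L, tol_speed = 0.05, reduction_min = 50) {
  if (!length(presets)) {
    return(data.frame(metric = character(0), genotype = character(0),
                      expected = numeric(0), recovered = numeric(0),
                      tol = numeric(0), pass = logical(0)))
  }
  need_wt <- any(presets != "WT")
  all_presets <- unique(c(if (need_wt) "WT", presets))
  runs <- lapply(all_presets, function(nm) run_quantify(nm, seed = seed))
  names(runs) <- all_presets
  rows <- list()
  add <- function(metric, genotype, expected, recovered, tol, ge = FALSE) {
    pass <- if (ge) recovered >= expected else abs(recovered - expected) <= tol
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, genotype = genotype, expected = expected,
      recovered = recovered, tol = tol, pass = pass)
  }
  for (nm in presets) {
    p <- runs[[nm]]$preset
    k <- runs[[nm]]$kinetics
    add("closure duration (min)", nm, p$duration, k$duration, p$dt_closure)
    add("initial LE convergence speed (um/min)", nm,
        p$conv_knots[1L, "v"], k$conv_t0, tol_speed)
    add("max LE convergence speed (um/min)", nm,
        max(p$conv_knots[, "v"]), k$max_conv, tol_speed)
    add("zipping speed at t0 (um/min)", nm,
        p$zip_knots[1L, "v"], k$zip_t0, tol_speed)
    add("mean zipping speed 0-84 min (um/min)", nm,
        profile_integral(p$zip_knots, 84) / 84, k$mean_zip_0_84, tol_speed)
    first_ts <- c(p$zip_knots[p$zip_knots[, "t"] <= 150, "t"],
                  min(150, p$duration))
    add("first-phase max zipping speed (um/min)", nm,
        max(profile_speed(p$zip_knots, first_ts)),
        k$max_zip_first_phase, tol_speed)
    if (nm != "WT") {
      amp_wt <- mean(runs[["WT"]]$pulsation$summary$amplitude)
      amp_mut <- mean(runs[[nm]]$pulsation$summary$amplitude)
      add("AS pulse amplitude reduction (%)", nm, reduction_min,
          100 * (1 - amp_mut / amp_wt), NA_real_, ge = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
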