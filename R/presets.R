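#' Registered experiment presets
#'
#' Named protocols wrapping the package's analysis functions: an influx step
#' onto the jammed plateau (\code{fig2a}), the relaxation-time scan
#' (\code{fig2b-scan}), phase-plane nullclines below/at/above the threshold
#' (\code{fig3-nullclines}), the driven-influx response map
#' (\code{fig4-sweep}), the Fano-factor sweep over the carrier pool
#' (\code{fig5-sweep}), the carrier-ratio perturbation (\code{s1fig}), the
#' double-Michaelis-Menten random walk (\code{s6fig}) and the coupled-pool
#' influx step (\code{s8fig}).
#'
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  c("fig2a", "fig2b-scan", "fig3-nullclines", "fig4-sweep", "fig5-sweep",
    "s1fig", "s6fig", "s8fig")
}

#' Run an experiment preset
#'
#' Executes the named protocol with the package defaults (overridable),
#' writes its trajectory/table outputs as TSV and a summary report as JSON
#' into \code{output_dir}, and returns the summary.  Stochastic presets are
#' reproducible given \code{seed}.
#'
#' @param name a preset from \code{\link{list_presets}}.
#' @param output_dir directory for outputs (created if needed); \code{NULL}
#'   skips file output.
#' @param seed RNG seed for stochastic presets.
#' @param overrides named list of \code{\link{ccc_params}} fields to
#'   override.
#' @param scale size multiplier in (0, 1] shrinking grids/horizons for quick
#'   runs.
#' @return Named list with the preset's headline numbers.
#' @export
run_preset <- function(name, output_dir = NULL, seed = 1, overrides = list(),
                       scale = 1) {
  name <- match.arg(name, list_presets())
  stopifnot(scale > 0, scale <= 1)
  params <- do.call(ccc_update, c(list(ccc_params()), overrides))
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  emit <- function(obj, file) {
    if (!is.null(output_dir))
      write_trajectory(obj, file.path(output_dir, file))
  }
  summary <- switch(name,
    "fig2a" = {
      tr <- ccc_step_response(params, kin_before = 1.1, kin_after = 0.9,
                              pre_run = 100, t_end = ceiling(2000 * scale))
      emit(tr, "fig2a_trajectory.tsv")
      tau <- relaxation_time(tr)
      list(preset = name, kin_before = 1.1, kin_after = 0.9, tau = tau)
    },
    "fig2b-scan" = {
      kin_values <- c(0.90, 0.92, 0.94, 0.96, 0.97, 0.98)
      if (scale < 1) kin_values <- kin_values[kin_values <= 0.9 + 0.08 * scale]
      sc <- relaxation_scan(params, kin_values)
      emit(sc$rows, "fig2b_scan.tsv")
      list(preset = name, kin_th = sc$kin_th_used,
           fitted_exponent = sc$fitted_exponent)
    },
    "fig3-nullclines" = {
      grid <- seq(0.01, 1.99, length.out = max(20, round(80 * scale)))
      out <- lapply(c(A = 0.8, B = 0.984313, C = 1.2), function(kin)
        ccc_nullclines(ccc_update(params, kin = kin), cpool = 2, csum = 2,
                       m1_grid = grid))
      for (panel in names(out))
        emit(out[[panel]], sprintf("fig3_nullclines_%s.tsv", panel))
      ss <- ccc_steady_state(ccc_update(params, kin = 0.8), 2, 2)
      list(preset = name, kin_values = c(0.8, 0.984313, 1.2),
           fixed_point_m0_at_0.8 = ss$m0, fixed_point_m1_at_0.8 = ss$m1)
    },
    "fig4-sweep" = {
      p <- ccc_update(params, kleak = 1e-3)
      Ain <- c(0.1, 0.4, 0.7, 1.0)
      f <- 10^seq(-4, -1.5, length.out = max(4, round(10 * scale)))
      rm <- response_map(p, Ain, f, kin0 = 1)
      if (!is.null(output_dir)) {
        tab <- data.frame(f = rm$f_values, rm$response, check.names = FALSE)
        emit(tab, "fig4_response_map.tsv")
      }
      list(preset = name, Ain = Ain, cutoff_analytic = rm$cutoff_curve)
    },
    "fig5-sweep" = {
      cp <- round(c(25, 50, 100, 150, 300, 400, 600) *
                    ifelse(scale < 1, 0.5, 1))
      sw <- fano_pool_sweep(kin = 100, kc = params$kc, kp = params$kp,
                            cpool_values = cp,
                            t_end = 2000 * scale, burn_in = 100 * scale,
                            seed = seed)
      emit(sw, "fig5_pool_sweep.tsv")
      list(preset = name, fano_saturated = sw$fano[sw$saturated][1],
           fano_unsaturated = sw$fano[!sw$saturated][sum(!sw$saturated)],
           fano_analytic = fano_analytic(params$kc, params$kp))
    },
    "s1fig" = {
      p <- ccc_update(params, kin = 0.6)
      tr <- carrier_ratio_perturbation(p, ratio_active_after = 0.99,
                                       t_end = ceiling(2000 * scale))
      emit(tr, "s1fig_trajectory.tsv")
      list(preset = name, kin = 0.6, ratio_active_after = 0.99,
           tau = relaxation_time(tr))
    },
    "s6fig" = {
      set.seed(seed)
      paths <- lapply(1:3, function(i)
        ssa_double_mm(kc = 1, kp = 1, c1 = 100, c2 = 100, n0 = 100,
                      t_end = 50 * scale))
      if (!is.null(output_dir))
        for (i in seq_along(paths))
          emit(data.frame(time = paths[[i]]$time, n = paths[[i]]$n),
               sprintf("s6fig_path%d.tsv", i))
      list(preset = name, kc = 1, kp = 1, c1 = 100, c2 = 100,
           final_counts = vapply(paths, function(s) s$n[length(s$n)],
                                 numeric(1)))
    },
    "s8fig" = {
      casc2 <- ccc_update(params, kin = 1, K0 = 1e2)
      cp <- coupled_params(list(params, casc2))
      tr <- coupled_step_response(cp, kin1_before = 1.1, kin1_after = 0.9,
                                  pre_run = 100, t_end = ceiling(2000 * scale))
      emit(tr, "s8fig_trajectory.tsv")
      list(preset = name, kin2 = 1, K02 = 1e2,
           tau = relaxation_time(tr))
    })
  if (!is.null(output_dir)) {
    meta <- list(seed = seed, scale = scale,
                 package_version = as.character(utils::packageVersion("cccsim")),
                 params_digest = paste(names(unclass(params)),
                                       sprintf("%.12g", unlist(params)),
                                       sep = "=", collapse = ";"))
    write_report(c(summary, meta),
                 file.path(output_dir, paste0(gsub("-", "_", name),
                                              "_summary.json")))
  }
  summary
}
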