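# End-to-end cohort pipeline: sample paired cases, build phantoms, mesh,
# solve, extract metrics, run the statistics layer, write artifacts.

#' Pipeline configuration
#'
#' Aggregates the cohort size and seed, waveform parameters, grid
#' resolution and solver numerics, and output flags. Geometry is in
#' mm/cm^2/cm^3, the waveform in mL and s; the solver converts to SI
#' internally.
#'
#' @param n number of paired cases
#' @param seed master seed; all randomness flows from it
#' @param tidal_volume mL
#' @param period respiratory cycle, s
#' @param ie_ratio inspiratory:expiratory ratio
#' @param nz,nr,grading grid resolution for the per-case solves
#' @param scheme,alpha_u,alpha_p,tol,max_iter solver numerics
#' @param gravity_enabled include gravity as an axial body force
#' @param hydro_correct report hydrostatic-corrected pressures
#' @param force_unconverged extract metrics from unconverged fields
#'   instead of dropping the case
#' @param measurement_error emulate the study's double-measurement
#'   protocol on the extracted metrics (see [measure_cohort()])
#' @param write_fields also write STL/VTK artifacts per case
#' @param out_dir output directory; `NULL` for in-memory only
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(n = 30, seed = 20170407, tidal_volume = 600,
                            period = 4, ie_ratio = 1,
                            nz = 96, nr = 16, grading = 1.15,
                            scheme = "second_upwind", alpha_u = 0.7,
                            alpha_p = 0.3, tol = 1e-4, max_iter = 1000,
                            gravity_enabled = TRUE, hydro_correct = TRUE,
                            force_unconverged = FALSE,
                            measurement_error = TRUE,
                            write_fields = FALSE, out_dir = NULL) {
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              tidal_volume = tidal_volume, period = period,
              ie_ratio = ie_ratio, nz = as.integer(nz),
              nr = as.integer(nr), grading = grading, scheme = scheme,
              alpha_u = alpha_u, alpha_p = alpha_p, tol = tol,
              max_iter = as.integer(max_iter),
              gravity_enabled = isTRUE(gravity_enabled),
              hydro_correct = isTRUE(hydro_correct),
              force_unconverged = isTRUE(force_unconverged),
              measurement_error = isTRUE(measurement_error),
              write_fields = isTRUE(write_fields), out_dir = out_dir)
  structure(cfg, class = "pipeline_config")
}

metrics_row <- function(m, suffix) {
  keep <- c("V_na", "V_or", "V_hy", "A_min", "a_ratio",
            "dP_max", "dP_na", "dP_or", "dP_hy")
  vals <- unlist(m[keep])
  names(vals) <- paste0(keep, "_", suffix)
  as.data.frame(as.list(vals))
}

#' Run the full pre/post cohort pipeline
#'
#' For each sampled paired case: build both phantoms, mesh, solve the
#' steady peak-inspiration flow (V = Q/A at the case's own inlet area),
#' sweep slices and compute metrics; then assemble the cohort table, run
#' the paired tests with Holm correction and the correlation table, and
#' (optionally) write CSV/JSON/STL/VTK artifacts plus a run manifest.
#' Cases whose solves fail to converge are excluded with a logged reason;
#' the pipeline errors only if more than 20% of cases fail.
#'
#' @param config a [pipeline_config()]
#' @param params cohort generator parameters; default [cohort_params()]
#'   reseeded from the config
#' @return list: `table` (cohort data.frame), `tests`, `correlations`,
#'   `failed` (case indices), `manifest`
#' @export
run_pipeline <- function(config = pipeline_config(),
                         params = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (is.null(params)) params <- cohort_params(seed = config$seed)
  cases <- sample_cohort(params, config$n, seed = config$seed)
  q_peak <- peak_flow_rate(config$tidal_volume, config$period,
                           config$ie_ratio)
  fluid <- fluid_props(gravity_enabled = config$gravity_enabled)
  numerics <- numerics_config(scheme = config$scheme,
                              alpha_u = config$alpha_u,
                              alpha_p = config$alpha_p, tol = config$tol,
                              max_iter = config$max_iter)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.json"))
  }
  rows <- list(); failed <- integer(0); fail_why <- character(0)
  all_metrics <- list()
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    res <- tryCatch({
      one <- lapply(list(t1 = case$pre, t2 = case$post), function(sp) {
        ph <- build_phantom(sp)
        r <- suppressWarnings(phantom_metrics(
          ph, q_peak = q_peak, nz = config$nz, nr = config$nr,
          grading = config$grading, fluid = fluid, numerics = numerics,
          hydro_correct = config$hydro_correct))
        if (!field_usable(r$field) && !config$force_unconverged) {
          stop("solver not converged (mass imbalance ",
               signif(r$field$mass_imbalance, 2), ")")
        }
        if (isTRUE(config$write_fields) && !is.null(out_dir)) {
          write_stl(ph, file.path(out_dir, sprintf("case%03d.stl", i)))
          write_vtk(r$grid, file.path(out_dir, sprintf("case%03d.vtk", i)),
                    r$field)
        }
        r
      })
      cbind(data.frame(case = i, ice = case$ice),
            metrics_row(one$t1$metrics, "t1"),
            metrics_row(one$t2$metrics, "t2"),
            data.frame(
              min_p_region_t1 = one$t1$metrics$min_pressure_region,
              min_p_region_t2 = one$t2$metrics$min_pressure_region))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, i)
      fail_why <- c(fail_why, conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (length(cases) > 0 && length(failed) > 0.2 * length(cases)) {
    stop("run_pipeline: ", length(failed), " of ", length(cases),
         " cases failed (> 20%): ",
         paste(unique(fail_why), collapse = "; "))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  sessions <- NULL
  if (isTRUE(config$measurement_error) && nrow(tab) > 0) {
    set.seed(config$seed + 1L)
    meas <- measure_cohort(tab, params)
    tab <- meas$averaged
    sessions <- meas$sessions
  }
  tests <- if (nrow(tab) >= 2) {
    cohort_paired_tests(tab, variables = c(
      "V_na", "V_or", "V_hy", "A_min", "a_ratio",
      "dP_max", "dP_na", "dP_or", "dP_hy"))
  } else NULL
  correlations <- if (nrow(tab) >= 3) cohort_correlations(tab) else NULL
  manifest <- list(
    seed = config$seed, n_requested = config$n,
    n_completed = nrow(tab), failed_cases = failed,
    failure_reasons = fail_why,
    package_version = as.character(utils::packageVersion("pharynxflow")),
    q_peak_mlps = q_peak,
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    utils::write.csv(tab, file.path(out_dir, "cohort_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(tests)) {
      utils::write.csv(tests, file.path(out_dir, "paired_tests.csv"),
                       row.names = FALSE)
    }
    if (!is.null(correlations)) {
      utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(table = tab, tests = tests, correlations = correlations,
       sessions = sessions, failed = failed, manifest = manifest)
}
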