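# Synthetic paired pre/post-treatment cohorts.
#
# Pre-treatment anatomy is drawn variable-by-variable from truncated normal
# distributions parameterized by the reference cohort means and SDs.
# Incisor retraction (ICE, mm) maps to post-treatment anatomy through a
# linear sensitivity model: fractional reduction = sensitivity x ICE +
# Gaussian noise, with the nasopharynx unchanged in expectation and the
# constriction relocating from the hypopharynx to the oropharynx.

#' Default cohort generator parameters
#'
#' Means and SDs of the pre-treatment anatomy (region volumes in cm^3,
#' A_min and inlet area in cm^2, region lengths in mm), the retraction
#' distribution ICE ~ N(6.84, 1.68^2) mm truncated at 0, and linear
#' sensitivities calibrated so that at the mean retraction the expected
#' post-treatment anatomy reproduces the reference post-treatment means
#' (V_or 20.83 -> 15.64, V_hy 8.50 -> 6.04, A_min 2.21 -> 1.51).
#'
#' @param seed integer seed recorded with the parameters
#' @return a `cohort_params` list
#' @export
cohort_params <- function(seed = 1L) {
  len <- default_region_lengths()
  p <- list(
    mean = c(v_na = 5.68, v_or = 20.83, v_hy = 8.50,
             a_min = 2.21, inlet_area = 2.50,
             len_na = unname(len[1]), len_or = unname(len[2]),
             len_hy = unname(len[3]), ice = 6.84),
    sd = c(v_na = 0.59, v_or = 4.86, v_hy = 3.44,
           a_min = 0.64, inlet_area = 0.30,
           len_na = 1.5, len_or = 4.0, len_hy = 2.5, ice = 1.68),
    # fractional reduction per mm of incisor retraction
    sens = c(v_or = (1 - 15.64 / 20.83) / 6.84,
             v_hy = (1 - 6.04 / 8.50) / 6.84,
             a_min = (1 - 1.51 / 2.21) / 6.84),
    noise_sd = 0.05,       # SD of the fractional-reduction noise
    na_noise_sd = 0.05,    # nasopharynx volume noise, mean unchanged
    trunc_frac = 0.10,     # truncated-normal lower bound, fraction of mean
    # method-error magnitudes of the manual double-measurement protocol
    # (Dahlberg ME): pressures in Pa, areas in mm^2, volumes in mm^3,
    # retraction in mm
    me_pressure = 0.47, me_area = 0.31, me_volume = 0.15, me_ice = 0.24,
    a_min_frac_pre = 0.5,
    # tongue-base level: the post-treatment constriction sits in the
    # inferior oropharynx, just above the C4-menton boundary plane
    a_min_frac_post = 0.85,
    # incisor retraction narrows a long stretch of the airway (tongue
    # pushed backward), not a localized notch: the post-treatment
    # constriction window spans this fraction of the oropharynx length
    post_halfwidth_frac = 0.55,
    headroom = 0.70,       # a_min must stay below headroom x region mean area
    seed = as.integer(seed)
  )
  stopifnot(all(p$sd >= 0), all(p$sens >= 0))
  structure(p, class = "cohort_params")
}

# truncated normal by rejection; lower bound only
rtrunc_norm <- function(n, mean, sd, lower) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
    guard <- guard + 1L
  }
  if (length(bad) > 0) x[bad] <- lower
  x
}

#' Map incisor retraction to post-treatment anatomy
#'
#' Linear reduction model applied to a pre-treatment specification:
#' oropharyngeal and hypopharyngeal volumes and A_min shrink by
#' `sens * ice` (fractionally) plus optional Gaussian noise; the
#' nasopharynx keeps its expected volume; the constriction moves to the
#' oropharynx. With `noise = FALSE` the mapping is deterministic and
#' monotone: larger `ice` never yields larger post volumes or A_min.
#'
#' @param pre a [phantom_spec()]
#' @param ice incisor retraction, mm (>= 0)
#' @param params a [cohort_params()]
#' @param noise logical; add the fractional-reduction noise terms
#' @return the post-treatment [phantom_spec()]
#' @export
apply_retraction <- function(pre, ice, params = cohort_params(),
                             noise = FALSE) {
  stopifnot(inherits(pre, "phantom_spec"), ice >= 0)
  eps <- function(sd) if (noise) stats::rnorm(1, 0, sd) else 0
  shrink <- function(x, s, sd) {
    f <- 1 - s * ice + eps(sd)
    x * min(1, max(0.05, f))
  }
  v_na <- pre$regions[[1]]$volume * max(0.05, 1 + eps(params$na_noise_sd))
  v_or <- shrink(pre$regions[[2]]$volume, params$sens[["v_or"]],
                 params$noise_sd)
  v_hy <- shrink(pre$regions[[3]]$volume, params$sens[["v_hy"]],
                 params$noise_sd)
  a_min <- shrink(pre$a_min, params$sens[["a_min"]], params$noise_sd)
  len <- vapply(pre$regions, function(r) r$length, numeric(1))
  # feasibility projection: the constriction must stay the global
  # minimum. The bound is the profile-family feasibility margin (the
  # renormalized base controls sit near the region mean areas), not the
  # generator's sampling headroom; the inlet control is pinned and only
  # needs a small margin.
  mean_area <- 10 * c(v_na, v_or, v_hy) / len
  cap <- min(0.9 * min(mean_area), 0.95 * pre$inlet_area)
  a_min <- min(a_min, cap)
  phantom_spec(
    regions = list(region_spec("nasopharynx", len[1], v_na),
                   region_spec("oropharynx", len[2], v_or),
                   region_spec("hypopharynx", len[3], v_hy)),
    a_min = a_min,
    a_min_region = if (ice > 0) "oropharynx" else pre$a_min_region,
    a_min_frac = if (ice > 0) params$a_min_frac_post else pre$a_min_frac,
    inlet_area = pre$inlet_area,
    constr_halfwidth = if (ice > 0) {
      params$post_halfwidth_frac * len[2]
    } else pre$constr_halfwidth)
}

#' Sample a synthetic paired pre/post cohort
#'
#' Draws `n` pre-treatment specifications from truncated normals, draws
#' ICE ~ N(ice_mean, ice_sd) truncated at 0, and derives each
#' post-treatment specification via [apply_retraction()] with noise.
#' Region lengths are projected per patient so that the drawn A_min is
#' feasible as the global minimum (lengths carry no cohort-level target;
#' volumes, A_min and ICE marginals are untouched by the projection).
#'
#' @param params a [cohort_params()]
#' @param n number of paired cases (>= 0)
#' @param seed overrides `params$seed` when given
#' @return list of `paired_case` objects, each with fields `pre`, `post`
#'   (phantom_spec) and `ice` (mm)
#' @export
sample_cohort <- function(params = cohort_params(), n, seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (n < 0) stop("sample_cohort: n must be >= 0")
  n <- as.integer(n)
  if (n == 0) return(list())
  set.seed(if (is.null(seed)) params$seed else as.integer(seed))
  m <- params$mean; s <- params$sd; lo <- params$trunc_frac
  draw <- function(key) rtrunc_norm(n, m[[key]], s[[key]], lo * m[[key]])
  v_na <- draw("v_na"); v_or <- draw("v_or"); v_hy <- draw("v_hy")
  a_min <- draw("a_min"); inlet <- draw("inlet_area")
  l_na <- draw("len_na"); l_or <- draw("len_or"); l_hy <- draw("len_hy")
  ice <- rtrunc_norm(n, m[["ice"]], s[["ice"]], 0)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    # shrink region lengths where needed so mean areas clear a_min
    # (length cap in mm = 10 * volume [cm^3] / required area [cm^2])
    need <- a_min[i] / params$headroom
    l_na_i <- min(l_na[i], 10 * v_na[i] / need)
    l_or_i <- min(l_or[i], 10 * v_or[i] / need)
    l_hy_i <- min(l_hy[i], 10 * v_hy[i] / need)
    inlet_i <- max(inlet[i], a_min[i] / 0.95)
    pre <- phantom_spec(
      regions = list(region_spec("nasopharynx", l_na_i, v_na[i]),
                     region_spec("oropharynx", l_or_i, v_or[i]),
                     region_spec("hypopharynx", l_hy_i, v_hy[i])),
      a_min = a_min[i], a_min_region = "hypopharynx",
      a_min_frac = params$a_min_frac_pre, inlet_area = inlet_i)
    post <- apply_retraction(pre, ice[i], params, noise = TRUE)
    out[[i]] <- structure(list(pre = pre, post = post, ice = ice[i]),
                          class = "paired_case")
  }
  out
}

#' Emulate the study's double-measurement protocol on a cohort table
#'
#' Every extracted metric was measured twice by the same examiner and the
#' average of the two sessions carried forward; the method error (Dahlberg
#' ME) of that protocol is documented per variable class. This helper
#' draws the two measurement sessions around each computed value with a
#' single-session SD equal to the ME (the Dahlberg ME of a session pair
#' with per-session SD sigma is sigma itself), floors physically
#' non-negative
#' quantities at zero, and returns both the session table (for
#' reliability statistics) and the averaged table (for the paired
#' analyses).
#'
#' @param tab cohort table from the pipeline (columns `<var>_t1`,
#'   `<var>_t2`, `ice`)
#' @param params a [cohort_params()] carrying the ME magnitudes
#' @return list: `averaged` (same shape as `tab`), `sessions` (long
#'   data.frame: case, variable, session1, session2)
#' @export
measure_cohort <- function(tab, params = cohort_params()) {
  me_of <- function(nm) {
    if (grepl("^dP", nm)) params$me_pressure
    else if (grepl("^A_min", nm)) params$me_area / 100      # mm^2 -> cm^2
    else if (grepl("^V_", nm)) params$me_volume / 1000      # mm^3 -> cm^3
    else if (nm == "ice") params$me_ice
    else 0
  }
  floor0 <- function(nm) grepl("^dP|^A_min|^V_|^ice$", nm)
  out <- tab
  sessions <- list()
  for (nm in names(tab)) {
    me <- me_of(sub("_t[12]$", "", nm))
    if (me <= 0) next
    s1 <- tab[[nm]] + stats::rnorm(nrow(tab), 0, me)
    s2 <- tab[[nm]] + stats::rnorm(nrow(tab), 0, me)
    if (floor0(sub("_t[12]$", "", nm))) {
      s1 <- pmax(s1, 0); s2 <- pmax(s2, 0)
    }
    out[[nm]] <- (s1 + s2) / 2
    sessions[[length(sessions) + 1]] <- data.frame(
      case = tab$case, variable = nm, session1 = s1, session2 = s2)
  }
  list(averaged = out, sessions = do.call(rbind, sessions))
}

#' @export
print.paired_case <- function(x, ...) {
  cat(sprintf(
    "Paired case: ICE %.2f mm; V_or %.2f -> %.2f cm^3, A_min %.2f -> %.2f cm^2\n",
    x$ice, x$pre$regions[[2]]$volume, x$post$regions[[2]]$volume,
    x$pre$a_min, x$post$a_min))
  invisible(x)
}
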