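#' Default synthetic study design
#'
#' The generator's default experimental conditions mirror the mouse
#' subarachnoid-hemorrhage (SAH) study the package models: three groups
#' (un-operated control, sham-operated, SAH) with group-specific plateau
#' flows, plateau knee pressures, resting pressures, tissue weights and
#' basal tissue perfusion. Plateau flows and basal perfusion are the
#' published group means (ipsilateral cortex 174.8 / 180.5 / 116.9
#' ml/100 g/min for control / sham / SAH); resting pressures are the group
#' mean arterial pressures (110.5 / 103.7 / 101.8 mmHg); plateau knees sit
#' at the measured autoregulatory limits of each group. Spleen and kidney
#' perfusion are set to literature-typical rodent values, equal across
#' groups, since SAH left them unchanged; they are synthetic placeholders,
#' not published means.
#'
#' Pressure sweeps cover 40-190 mmHg with 50 points; trace noise defaults
#' to 5% of the plateau signal; microsphere dispersion defaults to
#' per-group coefficients of variation back-computed from the published
#' SEMs (control 0.259, sham 0.121, SAH 0.179). Per-animal arbitrary-unit
#' gains are lognormal (sdlog 0.3) around 1.
#'
#' @param n_trace_animals Named integer vector: sweep animals per group
#'   (defaults control 5, sham 4, SAH 6).
#' @param n_sphere_animals Named integer vector: microsphere animals per
#'   group (defaults control 6, sham 6, SAH 7).
#' @param noise_frac Trace noise SD as a fraction of each group's plateau
#'   signal (default 0.05).
#' @param microsphere_cv Microsphere coefficient of variation: a single
#'   value for all groups or a named per-group vector (default the
#'   paper-spread-matched `c(control = 0.259, sham = 0.121, SAH = 0.179)`).
#' @param n_points Samples per sweep (default 50).
#' @param seed Integer master seed.
#' @return A list of class `study_design` with per-group model,
#'   measurement and protocol settings plus microsphere parameters.
#' @export
default_study_design <- function(n_trace_animals = c(control = 5, sham = 4,
                                                     SAH = 6),
                                 n_sphere_animals = c(control = 6, sham = 6,
                                                      SAH = 7),
                                 noise_frac = 0.05,
                                 microsphere_cv = c(control = 0.259,
                                                    sham = 0.121,
                                                    SAH = 0.179),
                                 n_points = 50,
                                 seed = 20260101L) {
  groups <- list(
    control = list(
      model = autoreg_model(plateau_flow = 174.8, lower_limit_bp = 77.3,
                            upper_limit_bp = 135.0),
      baseline_bp = 110.5,
      true_flows = c(cortex_ipsi = 174.8, cortex_contra = 181.2,
                     cerebellum = 398.1, spleen = 250, kidney = 600),
      tissue_weights = c(cortex_ipsi = 120.8, cortex_contra = 118.3,
                         cerebellum = 56.0, spleen = 69.3, kidney = 167.3)),
    sham = list(
      model = autoreg_model(plateau_flow = 180.5, lower_limit_bp = 78.2,
                            upper_limit_bp = 137.0),
      baseline_bp = 103.7,
      true_flows = c(cortex_ipsi = 180.5, cortex_contra = 177.5,
                     cerebellum = 404.9, spleen = 250, kidney = 600),
      tissue_weights = c(cortex_ipsi = 115.2, cortex_contra = 121.7,
                         cerebellum = 57.7, spleen = 71.2, kidney = 203.7)),
    SAH = list(
      model = autoreg_model(plateau_flow = 116.9, lower_limit_bp = 80.5,
                            upper_limit_bp = 122.2),
      baseline_bp = 101.8,
      true_flows = c(cortex_ipsi = 116.9, cortex_contra = 119.8,
                     cerebellum = 237.7, spleen = 250, kidney = 600),
      tissue_weights = c(cortex_ipsi = 128.3, cortex_contra = 127.0,
                         cerebellum = 59.7, spleen = 53.1, kidney = 176.4)))
  for (g in names(groups)) {
    groups[[g]]$n_trace_animals <- unname(n_trace_animals[g])
    groups[[g]]$n_sphere_animals <- unname(n_sphere_animals[g])
  }
  structure(list(groups = groups,
                 noise_frac = noise_frac,
                 microsphere_cv = microsphere_cv,
                 gain_sdlog = 0.3,
                 n_points = as.integer(n_points),
                 bp_min = 40, bp_max = 190,
                 withdrawal_rate = 0.1,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Simulate a complete study from a design
#'
#' Generates every group's pressure-sweep traces and microsphere records
#' plus a ground-truth record. All randomness (per-animal gains, trace
#' noise, microsphere dispersion) derives from the design's single master
#' seed, so two runs with the same design are identical.
#'
#' @param design A [default_study_design()] (possibly modified).
#' @return A list of class `study_data`: `traces` (long-format data frame),
#'   `microspheres` (record data frame), and `truth` (per-group generating
#'   parameters, including each group's true +/-20% limit crossings).
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  traces <- list(); spheres <- list(); truth <- list()
  gi <- 0L
  for (g in names(design$groups)) {
    gi <- gi + 1L
    gr <- design$groups[[g]]
    protocol <- sweep_protocol(design$bp_min, design$bp_max,
                               gr$baseline_bp, design$n_points)
    base_seed <- (design$seed + 7919L * gi) %% .Machine$integer.max
    gains <- with_seed(base_seed,
                       stats::rlnorm(gr$n_trace_animals, 0,
                                     design$gain_sdlog))
    for (a in seq_len(gr$n_trace_animals)) {
      meas <- measurement_model(
        au_gain = gains[a],
        noise_sd_au = design$noise_frac * gr$model$plateau_flow * gains[a],
        seed = (base_seed + a) %% .Machine$integer.max)
      tr <- simulate_trace(gr$model, meas, protocol,
                           animal_id = sprintf("%s_%02d", g, a), group = g)
      traces[[length(traces) + 1L]] <-
        data.frame(animal_id = attr(tr, "animal_id"), group = g,
                   map_mmHg = tr$map_mmHg, cbf_au = tr$cbf_au,
                   stringsAsFactors = FALSE)
    }
    cv_g <- if (length(design$microsphere_cv) > 1)
      design$microsphere_cv[[g]] else design$microsphere_cv
    sph_meas <- measurement_model(
      microsphere_cv = cv_g,
      seed = (base_seed + 1000L) %% .Machine$integer.max)
    spheres[[g]] <- simulate_microsphere_experiment(
      gr$true_flows, sph_meas, gr$n_sphere_animals,
      design$withdrawal_rate, gr$tissue_weights, group = g)
    tl <- true_autoreg_limits(gr$model)
    truth[[g]] <- list(
      plateau_flow = gr$model$plateau_flow,
      lower_knee_bp = gr$model$lower_limit_bp,
      upper_knee_bp = gr$model$upper_limit_bp,
      true_lower_bp = unname(tl["lower_bp"]),
      true_upper_bp = unname(tl["upper_bp"]),
      true_range_width = unname(tl["upper_bp"] - tl["lower_bp"]),
      baseline_bp = gr$baseline_bp,
      true_flows = as.list(gr$true_flows),
      n_trace_animals = gr$n_trace_animals,
      n_sphere_animals = gr$n_sphere_animals)
  }
  structure(list(traces = do.call(rbind, traces),
                 microspheres = do.call(rbind, spheres),
                 truth = truth,
                 design = design),
            class = "study_data")
}
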