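#' Paired pressure--flow trace from one animal
#'
#' A `flow_trace` holds simultaneous samples of mean arterial pressure
#' (mmHg) and relative cerebral blood flow (arbitrary units) collected while
#' blood pressure is swept, as produced by laser-Doppler flowmetry. It is a
#' data frame with columns `map_mmHg` and `cbf_au` plus `animal_id` and
#' `group` attributes.
#'
#' At least 8 samples are required and pressures must be positive with
#' non-negative flow. Fitting eligibility (pressure span, distinct
#' pressures) is enforced by [fit_curve()].
#'
#' @param animal_id Identifier of the animal.
#' @param group Group label (e.g. `"control"`, `"sham"`, `"SAH"`).
#' @param map_mmHg Numeric vector of mean arterial pressures (mmHg).
#' @param cbf_au Numeric vector of relative flows (a.u.), same length.
#' @return An object of classes `flow_trace` and `data.frame`.
#' @export
flow_trace <- function(animal_id, group, map_mmHg, cbf_au) {
  if (length(map_mmHg) != length(cbf_au))
    stop("`map_mmHg` and `cbf_au` must have the same length")
  if (length(map_mmHg) < 8)
    stop("a trace needs at least 8 samples")
  if (any(!is.finite(map_mmHg)) || any(map_mmHg <= 0))
    stop("all pressures must be positive and finite (mmHg)")
  if (any(!is.finite(cbf_au)) || any(cbf_au < 0))
    stop("all flow values must be non-negative and finite (a.u.)")
  out <- data.frame(map_mmHg = as.numeric(map_mmHg),
                    cbf_au = as.numeric(cbf_au))
  attr(out, "animal_id") <- as.character(animal_id)
  attr(out, "group") <- as.character(group)
  class(out) <- c("flow_trace", "data.frame")
  out
}

#' @export
print.flow_trace <- function(x, ...) {
  cat(sprintf("Flow trace %s (%s): %d samples, MAP %.1f-%.1f mmHg\n",
              attr(x, "animal_id"), attr(x, "group"), nrow(x),
              min(x$map_mmHg), max(x$map_mmHg)))
  invisible(x)
}

#' Split a long-format trace table into flow traces
#'
#' Converts a data frame with columns `animal_id`, `group`, `map_mmHg`,
#' `cbf_au` (the trace CSV layout) into a list of [flow_trace()] objects,
#' one per animal.
#'
#' @param df Data frame in long trace format.
#' @return Named list of `flow_trace` objects, keyed by `animal_id`.
#' @export
as_flow_traces <- function(df) {
  need <- c("animal_id", "group", "map_mmHg", "cbf_au")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trace table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  parts <- split(df, df$animal_id)
  out <- lapply(parts, function(p)
    flow_trace(p$animal_id[1], p$group[1], p$map_mmHg, p$cbf_au))
  out[order(names(out))]
}
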