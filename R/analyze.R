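#' Fit, calibrate and summarise autoregulation across a group of animals
#'
#' Runs the full curve analysis over a collection of traces. In
#' `per_animal` mode (the default, matching per-animal limit statistics)
#' each trace is fitted with its own cubic, calibrated against its group's
#' baseline anchor, and its limits extracted; the group summary is the mean
#' +/- SEM of the per-animal limits and range widths, excluding censored
#' limits with a logged count. In `pooled` mode all samples of a group are
#' concatenated into a single fit (the display-style group curve) yielding
#' one set of limits per group.
#'
#' The baseline anchor is group-level because microsphere perfusion and
#' pressure sweeps come from separately instrumented animals: `baselines`
#' maps each group to its resting pressure and its microsphere baseline
#' flow.
#'
#' @param traces A list of [flow_trace()] objects, or a long-format trace
#'   data frame (see [as_flow_traces()]).
#' @param baselines Data frame with columns `group`, `baseline_bp` (mmHg)
#'   and `baseline_cbf_abs` (ml/100 g/min); one row per group present.
#' @param mode `"per_animal"` or `"pooled"`.
#' @param fraction Autoregulatory band half-width (default 0.20).
#' @param alpha Significance level for the across-group comparisons.
#' @return A list of class `autoreg_analysis`:
#'   \describe{
#'     \item{limits}{per-animal (or per-group, pooled mode) limit table}
#'     \item{summary}{per-group mean, SEM and n of `lower_bp`, `upper_bp`
#'       and `range_width` (per-animal mode)}
#'     \item{comparisons}{ANOVA/Tukey across groups for each metric, when
#'       at least two groups have n >= 2}
#'     \item{censored}{count of censored limits excluded per group}
#'   }
#' @export
analyze_group <- function(traces, baselines,
                          mode = c("per_animal", "pooled"),
                          fraction = 0.20, alpha = 0.05) {
  mode <- match.arg(mode)
  if (is.data.frame(traces) && !inherits(traces, "flow_trace"))
    traces <- as_flow_traces(traces)
  if (inherits(traces, "flow_trace")) traces <- list(traces)
  need <- c("group", "baseline_bp", "baseline_cbf_abs")
  if (!all(need %in% names(baselines)))
    stop("`baselines` needs columns: ", paste(need, collapse = ", "))

  trace_groups <- vapply(traces, attr, "", "group")
  missing_base <- setdiff(unique(trace_groups), baselines$group)
  if (length(missing_base))
    stop("no baseline anchor for group(s): ",
         paste(missing_base, collapse = ", "))

  anchor <- function(g) baselines[match(g, baselines$group), ]

  if (mode == "pooled") {
    traces <- lapply(split(traces, trace_groups), function(tt) {
      df <- do.call(rbind, lapply(tt, as.data.frame))
      flow_trace(paste0("pooled_", attr(tt[[1]], "group")),
                 attr(tt[[1]], "group"), df$map_mmHg, df$cbf_au)
    })
  }

  limit_objs <- lapply(traces, function(tr) {
    b <- anchor(attr(tr, "group"))
    cur <- fit_curve(tr)
    cur <- calibrate(cur, b$baseline_cbf_abs, b$baseline_bp)
    find_limits(cur, fraction = fraction)
  })

  limits <- do.call(rbind, lapply(limit_objs, function(l)
    data.frame(animal_id = l$animal_id, group = l$group,
               lower_bp = l$lower_bp, upper_bp = l$upper_bp,
               range_width = l$range_width,
               lower_censored = l$lower_censored,
               upper_censored = l$upper_censored,
               stringsAsFactors = FALSE)))
  rownames(limits) <- NULL

  censored <- stats::aggregate(
    cbind(n_censored = lower_censored | upper_censored) ~ group,
    data = limits, FUN = sum)
  if (any(censored$n_censored > 0))
    message(sprintf("excluding censored limits from summaries: %s",
                    paste(sprintf("%s: %d", censored$group,
                                  censored$n_censored), collapse = ", ")))

  summary_df <- NULL
  comparisons <- NULL
  if (mode == "per_animal") {
    ok <- limits[!limits$lower_censored & !limits$upper_censored, ]
    if (nrow(ok) == 0)
      stop("all limits censored in every group: summary undefined")
    metrics <- c("lower_bp", "upper_bp", "range_width")
    summary_df <- do.call(rbind, lapply(split(ok, ok$group), function(g) {
      if (nrow(g) < 2) return(NULL)  # SEM undefined for a single animal
      do.call(rbind, lapply(metrics, function(m) {
        s <- summarize_group(g[[m]], group = g$group[1], tissue = NA)
        data.frame(group = s$group, metric = m, mean = s$mean,
                   sem = s$sem, n = s$n, stringsAsFactors = FALSE)
      }))
    }))
    rownames(summary_df) <- NULL
    eligible <- names(which(table(ok$group) >= 2))
    if (length(eligible) >= 2) {
      sub <- ok[ok$group %in% eligible, ]
      comparisons <- lapply(stats::setNames(metrics, metrics), function(m)
        compare_groups(sub[[m]], sub$group, alpha = alpha))
    }
  }

  structure(list(limits = limits, summary = summary_df,
                 comparisons = comparisons, censored = censored,
                 mode = mode, fraction = fraction),
            class = "autoreg_analysis")
}

#' @export
print.autoreg_analysis <- function(x, ...) {
  cat(sprintf("Autoregulation analysis (%s mode, +/-%.0f%% band)\n",
              x$mode, 100 * x$fraction))
  cat(sprintf("  %d fitted curves across %d group(s)\n",
              nrow(x$limits), length(unique(x$limits$group))))
  if (!is.null(x$summary)) {
    cat("  group summaries (mean +/- SEM, mmHg):\n")
    for (i in seq_len(nrow(x$summary)))
      cat(sprintf("    %s %s: %.1f +/- %.1f (n = %d)\n",
                  x$summary$group[i], x$summary$metric[i],
                  x$summary$mean[i], x$summary$sem[i], x$summary$n[i]))
  }
  invisible(x)
}
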