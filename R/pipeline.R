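#' Pipeline configuration
#'
#' Collects the tunable analysis settings: the autoregulatory band
#' half-width (default +/-20% of baseline flow), the polynomial degree
#' (fixed at 3 for the analysis, exposed for sensitivity checks), the
#' summary mode, the significance level and the master seed.
#'
#' @param autoreg_fraction Band half-width in (0, 1); default 0.20.
#' @param fit_degree Polynomial degree (>= 1); default 3.
#' @param mode `"per_animal"` or `"pooled"`.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param seed Integer master seed.
#' @param out_dir Output directory for the `run_*` stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(autoreg_fraction = 0.20, fit_degree = 3,
                            mode = c("per_animal", "pooled"),
                            alpha = 0.05, seed = 20260101L,
                            out_dir = ".") {
  mode <- match.arg(mode)
  if (autoreg_fraction <= 0 || autoreg_fraction >= 1)
    stop("`autoreg_fraction` must be in (0, 1)")
  if (fit_degree < 1) stop("`fit_degree` must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  structure(list(autoreg_fraction = autoreg_fraction,
                 fit_degree = as.integer(fit_degree), mode = mode,
                 alpha = alpha, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

config_provenance <- function(config) {
  cfg <- unclass(config)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  list(config = cfg,
       config_hash = unname(tools::md5sum(tmp)),
       package_version = as.character(utils::packageVersion("cbfautoreg")),
       schema_version = "1.0",
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Simulate stage: write synthetic traces, microsphere records and truth
#'
#' Runs [simulate_study()] on a design and writes the trace CSV, the
#' microsphere CSV and a ground-truth JSON sidecar (for recovery tests)
#' into `config$out_dir`.
#'
#' @param config A [pipeline_config()]; its `seed` overrides the design's.
#' @param design A [default_study_design()]; defaults to the standard
#'   three-group design under the config's seed.
#' @return Invisibly, the `study_data` with a `files` attribute naming the
#'   three outputs.
#' @export
run_simulate <- function(config, design = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(design)) design <- default_study_design(seed = config$seed)
  design$seed <- config$seed
  study <- simulate_study(design)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(config$out_dir,
                     c(traces = "traces.csv",
                       microspheres = "microspheres.csv",
                       truth = "truth.json"))
  names(files) <- c("traces", "microspheres", "truth")
  utils::write.csv(study$traces, files["traces"], row.names = FALSE)
  utils::write.csv(study$microspheres, files["microspheres"],
                   row.names = FALSE)
  jsonlite::write_json(c(list(provenance = config_provenance(config)),
                         study$truth),
                       files["truth"], auto_unbox = TRUE, digits = NA)
  attr(study, "files") <- files
  invisible(study)
}

#' Quantify stage: microsphere records to absolute flows and summaries
#'
#' Reads a microsphere CSV (or takes the records directly), validates each
#' row against the record invariants (rejections are logged and counted,
#' never silent), computes absolute perfusion per record, summarises each
#' group x tissue as mean +/- SEM, and runs ANOVA/Tukey across groups per
#' tissue. Writes a per-animal flows CSV and a summary JSON report with
#' provenance.
#'
#' @param config A [pipeline_config()].
#' @param microspheres Path to a microsphere CSV, or a record data frame.
#' @return Invisibly, a list with `flows`, `summaries`, `comparisons` and
#'   the output `files`.
#' @export
run_quantify <- function(config, microspheres) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- if (is.character(microspheres)) {
    if (!file.exists(microspheres))
      stop("cannot read microsphere file: ", microspheres)
    utils::read.csv(microspheres, stringsAsFactors = FALSE)
  } else as.data.frame(microspheres)
  need <- c("animal_id", "group", "tissue", "fluor_tissue", "fluor_ref",
            "withdrawal_rate_ml_min", "tissue_weight_mg")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("microsphere input is missing columns: ",
         paste(missing_cols, collapse = ", "))
  records <- validate_microsphere_records(records)
  if (nrow(records) == 0)
    stop("no valid microsphere records after validation")

  flows <- data.frame(animal_id = records$animal_id,
                      group = records$group, tissue = records$tissue,
                      flow_ml_100g_min = compute_blood_flow(records),
                      stringsAsFactors = FALSE)

  cells <- split(flows, list(flows$group, flows$tissue), drop = TRUE)
  summaries <- do.call(rbind, lapply(cells, function(cell)
    summarize_group(cell$flow_ml_100g_min, cell$group[1], cell$tissue[1])))
  rownames(summaries) <- NULL

  comparisons <- list()
  for (tis in unique(flows$tissue)) {
    sub <- flows[flows$tissue == tis, ]
    if (length(unique(sub$group)) >= 2 && all(table(sub$group) >= 2))
      comparisons[[tis]] <- compare_groups(sub$flow_ml_100g_min, sub$group,
                                           alpha = config$alpha)
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(config$out_dir, c(flows = "flows.csv",
                                       summary = "flow_summary.json"))
  names(files) <- c("flows", "summary")
  utils::write.csv(flows, files["flows"], row.names = FALSE)
  report <- list(
    provenance = config_provenance(config),
    n_records_in = nrow(records) + nrow(attr(records, "rejected")),
    n_records_used = nrow(records),
    rejected = attr(records, "rejected"),
    summaries = summaries,
    comparisons = lapply(comparisons, function(cmp)
      list(f_statistic = cmp$f_statistic, anova_p = cmp$anova_p,
           pairwise = cmp$pairwise)))
  jsonlite::write_json(report, files["summary"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(list(flows = flows, summaries = summaries,
                 comparisons = comparisons, files = files))
}

#' Build baseline anchors from a quantify-stage summary
#'
#' Pairs each group's resting mean arterial pressure with its microsphere
#' baseline flow (ipsilateral cortex mean) to form the calibration anchors
#' used by [run_autoreg()] / [analyze_group()].
#'
#' @param summaries Summary data frame from [run_quantify()] (or the path
#'   to its JSON report), holding per group x tissue means.
#' @param baseline_bp Named numeric vector mapping group to resting MAP
#'   (mmHg).
#' @param tissue Tissue whose mean anchors the calibration (default
#'   ipsilateral cortex).
#' @return Data frame with `group`, `baseline_bp`, `baseline_cbf_abs`.
#' @export
baselines_from_summary <- function(summaries,
                                   baseline_bp = c(control = 110.5,
                                                   sham = 103.7,
                                                   SAH = 101.8),
                                   tissue = "cortex_ipsi") {
  if (is.character(summaries))
    summaries <- as.data.frame(
      jsonlite::read_json(summaries, simplifyVector = TRUE)$summaries)
  sub <- summaries[summaries$tissue == tissue, ]
  if (nrow(sub) == 0)
    stop("no summaries for tissue ", tissue)
  missing_bp <- setdiff(sub$group, names(baseline_bp))
  if (length(missing_bp))
    stop("no baseline blood pressure for group(s): ",
         paste(missing_bp, collapse = ", "))
  data.frame(group = sub$group,
             baseline_bp = unname(baseline_bp[sub$group]),
             baseline_cbf_abs = sub$mean,
             stringsAsFactors = FALSE)
}

#' Autoregulation stage: traces to limits, summaries and comparisons
#'
#' Reads a trace CSV (or takes traces directly), runs
#' fit -> calibrate -> thresholds -> limits per the config mode via
#' [analyze_group()], and writes a per-animal limits CSV plus a group
#' report JSON (means +/- SEM, n, ANOVA/Tukey across groups for the lower
#' limit, upper limit and range width).
#'
#' @param config A [pipeline_config()].
#' @param traces Path to a trace CSV, or a long-format trace data frame.
#' @param baselines Anchor table from [baselines_from_summary()] (or a
#'   data frame with `group`, `baseline_bp`, `baseline_cbf_abs`).
#' @return Invisibly, the `autoreg_analysis` with a `files` attribute.
#' @export
run_autoreg <- function(config, traces, baselines) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(traces)) {
    if (!file.exists(traces)) stop("cannot read trace file: ", traces)
    traces <- utils::read.csv(traces, stringsAsFactors = FALSE)
  }
  trace_list <- if (is.data.frame(traces)) as_flow_traces(traces) else traces
  groups_present <- unique(vapply(trace_list, attr, "", "group"))
  missing_base <- setdiff(groups_present, baselines$group)
  if (length(missing_base))
    stop("missing baseline for group(s): ",
         paste(missing_base, collapse = ", "))

  analysis <- analyze_group(trace_list, baselines, mode = config$mode,
                            fraction = config$autoreg_fraction,
                            alpha = config$alpha)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(config$out_dir, c(limits = "limits.csv",
                                       report = "autoreg_report.json"))
  names(files) <- c("limits", "report")
  utils::write.csv(analysis$limits, files["limits"], row.names = FALSE)
  report <- list(
    provenance = config_provenance(config),
    mode = analysis$mode,
    fraction = analysis$fraction,
    baselines = baselines,
    summary = analysis$summary,
    censored = analysis$censored,
    comparisons = lapply(analysis$comparisons, function(cmp)
      list(f_statistic = cmp$f_statistic, anova_p = cmp$anova_p,
           pairwise = cmp$pairwise)))
  jsonlite::write_json(report, files["report"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  attr(analysis, "files") <- files
  invisible(analysis)
}
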