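#' Round values for reporting
#'
#' The `"paper"` profile matches conventional reporting precision in
#' Japanese cost-effectiveness submissions: QALYs at 4 decimals, JPY and USD
#' at whole units, relative effects at 2 decimals, proportions at 1 decimal
#' in percent. The `"none"` profile leaves full precision.
#'
#' @param x Numeric vector.
#' @param kind One of `"qaly"`, `"jpy"`, `"usd"`, `"relative_effect"`,
#'   `"percent"`.
#' @param profile `"paper"` or `"none"`.
#' @return Rounded numeric vector (percent inputs are fractions; output is
#'   in percent for `kind = "percent"`).
#' @export
round_for_report <- function(x, kind = c("qaly", "jpy", "usd",
                                         "relative_effect", "percent"),
                             profile = c("paper", "none")) {
  kind <- match.arg(kind)
  profile <- match.arg(profile)
  if (kind == "percent") x <- 100 * x
  if (profile == "none") return(x)
  digits <- switch(kind, qaly = 4, jpy = 0, usd = 0, relative_effect = 2,
                   percent = 1)
  round(x, digits)
}

#' Base-case results table
#'
#' One row per strategy with expected cost and QALYs, plus the incremental
#' columns (delta cost, delta QALYs, ICER or dominance label) for the
#' comparisons of the intervention against each comparator.
#'
#' @param results [evaluate_all()] output.
#' @param comparisons [compare_all()] output.
#' @param profile Rounding profile for [round_for_report()].
#' @param scenario Optional scenario label column.
#' @return A data.frame.
#' @export
base_case_table <- function(results, comparisons, profile = "none",
                            scenario = "base_case") {
  stopifnot(inherits(results, "strategy_results"))
  df <- as.data.frame(results)
  intervention <- setdiff(df$strategy, names(comparisons))
  df$delta_cost_jpy <- NA_real_
  df$delta_qaly <- NA_real_
  df$icer_jpy_per_qaly <- NA_real_
  df$label <- NA_character_
  for (cmp in comparisons) {
    i <- df$strategy == cmp$comparator
    # incremental columns read "intervention minus this row's strategy"
    df$delta_cost_jpy[i] <- cmp$delta_cost_jpy
    df$delta_qaly[i] <- cmp$delta_qaly
    df$icer_jpy_per_qaly[i] <- cmp$icer_jpy_per_qaly
    df$label[i] <- cmp$label
  }
  df$expected_cost_usd <- NA_real_
  df$scenario <- scenario
  if (profile == "paper") {
    df$expected_qaly <- round_for_report(df$expected_qaly, "qaly")
    df$expected_cost_jpy <- round_for_report(df$expected_cost_jpy, "jpy")
    df$delta_cost_jpy <- round_for_report(df$delta_cost_jpy, "jpy")
    df$delta_qaly <- round_for_report(df$delta_qaly, "qaly")
    df$icer_jpy_per_qaly <- round_for_report(df$icer_jpy_per_qaly, "jpy")
  }
  df
}

#' Write the full analysis output set
#'
#' Runs the requested analyses on a parameter set and writes plot-ready
#' tabular artifacts to a directory: `base_case.csv` / `base_case.json`
#' (strategy rows and comparison rows), `tornado_<comparator>.csv` per
#' comparison, `psa_samples.csv` (cost-effectiveness plane scatter),
#' `ceac.csv`, `psa_summary.json`, and `scenarios.csv`.
#'
#' @param params A validated [parameter_set()].
#' @param outdir Output directory (created if absent).
#' @param analysis `"base"`, `"owa"`, `"psa"`, `"scenarios"` or `"all"`.
#' @param seed Integer seed (required for the PSA).
#' @param profile Rounding profile.
#' @param intervention Strategy compared against the rest.
#' @return Invisibly, a character vector of the files written.
#' @export
write_analysis_outputs <- function(params, outdir,
                                   analysis = c("all", "base", "owa", "psa",
                                                "scenarios"),
                                   seed = NULL, profile = "paper",
                                   intervention = "lemborexant") {
  analysis <- match.arg(analysis)
  stopifnot(inherits(params, "parameter_set"))
  if (analysis %in% c("psa", "all") && is.null(seed)) {
    stop("a seed is required for the probabilistic sensitivity analysis",
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }

  results <- evaluate_all(params)
  comparisons <- compare_all(results, intervention)
  if (analysis %in% c("base", "all")) {
    tab <- base_case_table(results, comparisons, profile)
    emit(tab, "base_case.csv")
    path <- file.path(outdir, "base_case.json")
    jsonlite::write_json(tab, path, dataframe = "rows", na = "null",
                         digits = NA)
    written <- c(written, path)
    cmp_df <- do.call(rbind, lapply(comparisons, as.data.frame))
    emit(cmp_df, "comparisons.csv")
  }
  if (analysis %in% c("owa", "all")) {
    for (cmp in setdiff(strategies(), intervention)) {
      tor <- one_way_analysis(params, intervention, cmp)
      tor$outcome_metric <- attr(tor, "outcome_metric")
      tor$base_outcome <- attr(tor, "base_outcome")
      emit(as.data.frame(tor), paste0("tornado_", cmp, ".csv"))
    }
  }
  if (analysis %in% c("psa", "all")) {
    psa <- run_psa(params, seed = seed, intervention = intervention)
    summ <- psa_summary(psa)
    emit(ce_plane_data(psa), "psa_samples.csv")
    emit(summ$ceac, "ceac.csv")
    path <- file.path(outdir, "psa_summary.json")
    jsonlite::write_json(list(wtp = summ$wtp, seed = seed,
                              resamples = attr(psa, "resamples"),
                              summary = summ$summary),
                         path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    written <- c(written, path)
  }
  if (analysis %in% c("scenarios", "all")) {
    tabs <- lapply(names(standard_scenarios()), function(nm) {
      sc <- run_scenario(params, standard_scenarios()[[nm]], intervention)
      base_case_table(sc$results, sc$comparisons, profile, scenario = nm)
    })
    emit(do.call(rbind, tabs), "scenarios.csv")
  }
  invisible(written)
}

provenance_summary <- function(params) {
  prov <- vapply(params$specs, `[[`, "", "provenance")
  sprintf("parameters: %d printed, %d placeholder",
          sum(prov == "printed"), sum(prov == "placeholder"))
}

#' Command-line entry point
#'
#' Thin argv-driven wrapper over [load_parameter_set()] and
#' [write_analysis_outputs()], used by the shipped script
#' `system.file("cli", "insomnia_cea.R", package = "insomniaCEA")`.
#'
#' Flags: `--config <yaml>` (default: the packaged reference configuration),
#' `--analysis base|owa|psa|scenarios|all` (default `all`), `--seed <int>`,
#' `--outdir <dir>` (default `insomnia_cea_output`), `--wtp <jpy_per_qaly>`,
#' `--rounding paper|none`.
#'
#' @param argv Character vector of arguments (e.g. `commandArgs(TRUE)`).
#' @return Integer exit status, invisibly: 0 on success, 2 for an unreadable
#'   configuration, 3 for a validation failure.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  opts <- list(config = NULL, analysis = "all", seed = 1L,
               outdir = "insomnia_cea_output", wtp = NULL, rounding = "paper")
  i <- 1
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opts) || i == length(argv)) {
      message("usage: insomnia_cea.R [--config <yaml>] [--analysis base|owa|psa|scenarios|all]\n",
              "                      [--seed <int>] [--outdir <dir>] [--wtp <jpy>] [--rounding paper|none]")
      return(invisible(2L))
    }
    opts[[key]] <- argv[i + 1]
    i <- i + 2
  }
  if (!opts$analysis %in% c("base", "owa", "psa", "scenarios", "all")) {
    message("unknown analysis selector: ", opts$analysis)
    return(invisible(2L))
  }

  params <- tryCatch({
    if (is.null(opts$config)) {
      reference_parameters()
    } else if (!file.exists(opts$config)) {
      stop("config file not found: ", opts$config, call. = FALSE)
    } else {
      load_parameter_set(opts$config)
    }
  }, error = function(e) e)
  if (inherits(params, "error")) {
    message("configuration error: ", conditionMessage(params))
    return(invisible(if (grepl("not found|parse|scanner", conditionMessage(params))) 2L else 3L))
  }
  if (!is.null(opts$wtp)) {
    params <- tryCatch(
      set_param_value(params, "wtp_jpy_per_qaly", as.numeric(opts$wtp)),
      error = function(e) e)
    if (inherits(params, "error")) {
      message("validation error: ", conditionMessage(params))
      return(invisible(3L))
    }
  }
  message(provenance_summary(params))
  files <- write_analysis_outputs(params, opts$outdir, opts$analysis,
                                  seed = as.integer(opts$seed),
                                  profile = opts$rounding)
  message("wrote: ", paste(basename(files), collapse = ", "))
  invisible(0L)
}
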