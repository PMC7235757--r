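# Text rendering of the per-category and diagnostic-metric tables, and
# the thin command-line dispatcher the inst/cli/tirads.R script wraps.

# Percent formatting: full-precision fractions rendered with 2 decimals
# (round half to even, R's default).  Presentation only — never feeds
# computation.
fmt_pct <- function(x) {
  ifelse(is.na(x), "NA", formatC(round(100 * x, 2), format = "f", digits = 2))
}

#' Render a per-category table as text
#'
#' @param table Category table (see [category_table()]).
#' @return Character vector of lines.
#' @export
render_category_table <- function(table) {
  header <- sprintf("%-8s %6s %7s %10s %15s", "category", "total", "benign",
                    "malignant", "risk (%)")
  rows <- sprintf("%-8s %6d %7d %10d %15s", table$category, table$total,
                  table$benign, table$malignant,
                  fmt_pct(table$calculated_risk))
  c(paste0("System: ", attr(table, "system")), header, rows)
}

#' Render a diagnostic-metrics table as text
#'
#' @param metrics data.frame with a `system` column and fraction-valued
#'   `se, sp, ppv, npv, acc` columns (as from [compare_systems()]).
#' @return Character vector of lines (percent scale, 2 decimals, `NA` for
#'   undefined metrics).
#' @export
render_metrics_table <- function(metrics) {
  header <- sprintf("%-10s %8s %8s %8s %8s %8s",
                    "system", "Se", "Sp", "PPV", "NPV", "Acc")
  if (nrow(metrics) == 0L) return(header)
  rows <- sprintf("%-10s %8s %8s %8s %8s %8s", metrics$system,
                  fmt_pct(metrics$se), fmt_pct(metrics$sp),
                  fmt_pct(metrics$ppv), fmt_pct(metrics$npv),
                  fmt_pct(metrics$acc))
  c(header, rows)
}

# --- command-line dispatcher -------------------------------------------

cli_usage <- paste(
  "usage: tirads <subcommand> [options]",
  "subcommands:",
  "  classify  --system <eu|acr|horvath|french|french4d> --in <cohort.csv> --out <categories.csv> [--config <points.yaml>]",
  "  evaluate  --in <cohort.csv> | --from-counts <counts.csv> [--systems eu,acr,...] --out <report.json>",
  "  simulate  --n <int> --seed <int> --out <cohort.csv>",
  "  glm       --in <cohort.csv> --predictors a,b,c [--add doppler4d] --out <fit.json>",
  "  corr      --in <cohort.csv> --predictors a,b,c --out <corr.csv>",
  sep = "\n")

cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i],
                                         call. = FALSE)
    key <- sub("^--", "", args[i])
    opts[[key]] <- if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      i <- i + 1L
      args[i]
    } else TRUE
    i <- i + 1L
  }
  opts
}

cli_require <- function(opts, keys) {
  for (k in keys) {
    if (is.null(opts[[k]])) stop("missing required option --", k,
                                 call. = FALSE)
  }
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/tirads.R` script: subcommands
#' `classify`, `evaluate`, `simulate`, `glm`, `corr`.  Every output
#' artifact records the seed (where randomness is involved) so reruns
#' with an identical configuration are reproducible.
#'
#' @param args Character vector of command-line arguments (default: the
#'   actual command line).
#' @return Integer exit status, invisibly (0 on success).
#' @export
run_tirads_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) {
      message(cli_usage)
      return(invisible(1L))
    }
    sub <- args[1L]
    opts <- cli_opts(args[-1L])
    switch(sub,
      classify = cli_classify(opts),
      evaluate = cli_evaluate(opts),
      simulate = cli_simulate(opts),
      glm = cli_glm(opts),
      corr = cli_corr(opts),
      stop("unknown subcommand: ", sub, "\n", cli_usage, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_points <- function(opts) {
  if (is.null(opts$config)) return(acr_points())
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for --config", call. = FALSE)
  }
  cfg <- yaml::read_yaml(opts$config)
  pts <- acr_points()
  for (nm in intersect(names(cfg), names(pts))) {
    if (is.list(cfg[[nm]]) || !is.null(names(cfg[[nm]]))) {
      pts[[nm]][names(cfg[[nm]])] <- unlist(cfg[[nm]])
    } else {
      pts[[nm]] <- cfg[[nm]]
    }
  }
  pts
}

cli_classify <- function(opts) {
  cli_require(opts, c("system", "in", "out"))
  cohort <- read_cohort(opts[["in"]])
  extra <- if (identical(opts$system, "acr")) {
    list(points = cli_points(opts))
  } else list()
  label <- do.call(tirads_classify,
                   c(list(cohort, opts$system), extra))
  out <- data.frame(id = cohort$id, category = label,
                    test_positive = as.integer(binary_call(label, opts$system)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, opts$out, row.names = FALSE, quote = FALSE)
}

cli_evaluate <- function(opts) {
  cli_require(opts, "out")
  cmp <- if (!is.null(opts[["from-counts"]])) {
    comparison_from_tables(read_counts(opts[["from-counts"]]))
  } else {
    cli_require(opts, "in")
    systems <- if (is.null(opts$systems)) tirads_systems() else
      strsplit(opts$systems, ",")[[1L]]
    compare_systems(read_cohort(opts[["in"]]), systems)
  }
  writeLines(comparison_json(cmp, pretty = TRUE), opts$out)
  print(cmp)
}

cli_simulate <- function(opts) {
  cli_require(opts, c("n", "seed", "out"))
  params <- default_cohort_params()
  cohort <- generate_cohort(params, n = as.integer(opts$n),
                            seed = as.integer(opts$seed))
  write_cohort(cohort, opts$out)
  message("seed: ", opts$seed, "; wrote ", nrow(cohort), " records to ",
          opts$out)
}

cli_glm <- function(opts) {
  cli_require(opts, c("in", "predictors", "out"))
  cohort <- read_cohort(opts[["in"]])
  predictors <- strsplit(opts$predictors, ",")[[1L]]
  fit <- fit_logistic(design_matrix(cohort, predictors))
  payload <- list(predictors = predictors,
                  coefficients = as.list(fit$coefficients),
                  se = as.list(fit$se), wald_z = as.list(fit$wald_z),
                  p_values = as.list(fit$p_values),
                  deviance = fit$deviance, aic = fit$aic,
                  n_iter = fit$n_iter, converged = fit$converged)
  if (!is.null(opts$add)) {
    fit2 <- fit_logistic(design_matrix(cohort, c(predictors, opts$add)))
    cmp <- compare_models(fit, fit2,
                          labels = c("base", paste0("base+", opts$add)))
    payload$added <- opts$add
    payload$comparison <- list(deviance = as.list(cmp$deviance),
                               aic = as.list(cmp$aic),
                               n_iter = as.list(cmp$n_iter),
                               preferred_aic = cmp$preferred_aic)
  }
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), opts$out)
  print(fit)
}

cli_corr <- function(opts) {
  cli_require(opts, c("in", "predictors", "out"))
  cohort <- read_cohort(opts[["in"]])
  dm <- design_matrix(cohort, strsplit(opts$predictors, ",")[[1L]])
  utils::write.csv(correlation_matrix(dm), opts$out)
}
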