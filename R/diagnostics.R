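# Per-category contingency tables, confusion matrices, diagnostic metrics
# and calibration against published expected-risk bands.

#' Per-category contingency table
#'
#' Classifies a cohort under one system and tallies benign/malignant
#' pathology per category, with the calculated malignancy risk
#' (malignant/total) per row.  Rows cover the system's full assignable
#' scale, including empty categories.
#'
#' @param cohort Validated cohort data.frame; every record must carry a
#'   pathology label.
#' @param system One of [tirads_systems()].
#' @param ... Passed to [tirads_classify()].
#' @return data.frame `(category, total, benign, malignant,
#'   calculated_risk)` with attribute `"system"`; risk is `NA` for empty
#'   categories, never 0.
#' @export
category_table <- function(cohort, system, ...) {
  system <- match.arg(system, tirads_systems())
  if (anyNA(cohort$pathology)) {
    stop("pathology label missing for nodule(s): ",
         paste(cohort$id[is.na(cohort$pathology)], collapse = ", "),
         call. = FALSE)
  }
  label <- factor(tirads_classify(cohort, system, ...),
                  levels = system_scale(system))
  malignant <- as.vector(table(label[cohort$pathology == "malignant"]))
  benign <- as.vector(table(label[cohort$pathology == "benign"]))
  counts_table(data.frame(category = system_scale(system),
                          benign = benign, malignant = malignant,
                          stringsAsFactors = FALSE),
               system)
}

#' Build a category table from pre-aggregated counts
#'
#' Completes a `(category, benign, malignant)` count data.frame — the
#' shape in which published per-category results are reported — into a
#' full category table with totals and calculated risk.
#'
#' @param counts data.frame with columns `category`, `benign`, `malignant`.
#' @param system One of [tirads_systems()].
#' @return Category table as from [category_table()].
#' @export
counts_table <- function(counts, system) {
  system <- match.arg(system, tirads_systems())
  stopifnot(all(c("category", "benign", "malignant") %in% names(counts)))
  out <- data.frame(category = as.character(counts$category),
                    total = counts$benign + counts$malignant,
                    benign = counts$benign, malignant = counts$malignant,
                    stringsAsFactors = FALSE)
  out$calculated_risk <- ifelse(out$total > 0, out$malignant / out$total, NA_real_)
  out <- out[order(category_rank(out$category)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, system = system)
}

#' Read per-category count fixtures
#'
#' Reads a CSV with columns `system, category, benign, malignant`
#' (several systems may share one file) and returns one category table
#' per system.
#'
#' @param path CSV path.
#' @return Named list of category tables.
#' @export
read_counts <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(category = "character"))
  stopifnot(all(c("system", "category", "benign", "malignant") %in% names(raw)))
  sapply(unique(raw$system), function(s) {
    counts_table(raw[raw$system == s, , drop = FALSE], s)
  }, simplify = FALSE)
}

#' Confusion matrix at a system's operating threshold
#'
#' Splits a category table at the binary test-positive threshold:
#' malignant nodules in positive categories are true positives, benign
#' ones false positives, and complements below the threshold.
#'
#' @param table Category table (see [category_table()]).
#' @param threshold Threshold category; default the system's operating
#'   threshold.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion <- function(table, threshold = NULL) {
  system <- attr(table, "system")
  pos <- binary_call(table$category, system, threshold)
  c(tp = sum(table$malignant[pos]), fp = sum(table$benign[pos]),
    tn = sum(table$benign[!pos]), fn = sum(table$malignant[!pos]))
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive value, and
#' accuracy as fractions in \[0, 1\].  A metric whose denominator is zero
#' is `NA` (0/0 is not a performance value), never 0.
#'
#' @param cm Named vector `c(tp, fp, tn, fn)` as from [confusion()].
#' @return One-row data.frame `(se, sp, ppv, npv, acc)`.
#' @export
diagnostic_metrics <- function(cm) {
  cm <- as.numeric(cm[c("tp", "fp", "tn", "fn")])
  names(cm) <- c("tp", "fp", "tn", "fn")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  n <- sum(cm)
  data.frame(
    se  = ratio(cm[["tp"]], cm[["tp"]] + cm[["fn"]]),
    sp  = ratio(cm[["tn"]], cm[["tn"]] + cm[["fp"]]),
    ppv = ratio(cm[["tp"]], cm[["tp"]] + cm[["fp"]]),
    npv = ratio(cm[["tn"]], cm[["tn"]] + cm[["fn"]]),
    acc = ratio(cm[["tp"]] + cm[["tn"]], n)
  )
}

#' Published expected malignancy-risk bands
#'
#' Loads the expected per-category malignancy-risk bands of the five
#' systems (fractions; point expectations are encoded as `low == high`).
#'
#' @param path Optional path to an alternative bands CSV
#'   (`system, category, low, high`).
#' @return data.frame of bands.
#' @export
expected_risk_bands <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "expected_risk_bands.csv",
                        package = "tiradsx", mustWork = TRUE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(category = "character"))
}

#' Calibration of calculated risk against expected bands
#'
#' Compares each category's calculated malignancy risk with the system's
#' published expected band and flags it `below`, `inside`, `above`, or
#' `no data` (empty category).
#'
#' @param table Category table.
#' @param bands Expected-risk bands (default [expected_risk_bands()]).
#' @return data.frame `(category, total, calculated_risk, expected_low,
#'   expected_high, flag)`.
#' @export
calibration_report <- function(table, bands = expected_risk_bands()) {
  system <- attr(table, "system")
  bands <- bands[bands$system == system, , drop = FALSE]
  if (nrow(bands) == 0L) stop("no expected-risk bands for system ", system,
                              call. = FALSE)
  idx <- match(table$category, bands$category)
  out <- data.frame(category = table$category, total = table$total,
                    calculated_risk = table$calculated_risk,
                    expected_low = bands$low[idx],
                    expected_high = bands$high[idx],
                    stringsAsFactors = FALSE)
  out$flag <- ifelse(out$total == 0 | is.na(out$calculated_risk), "no data",
              ifelse(out$calculated_risk < out$expected_low, "below",
              ifelse(out$calculated_risk > out$expected_high, "above",
                     "inside")))
  structure(out, system = system)
}

#' Side-by-side evaluation of all systems
#'
#' Classifies a cohort under each requested system, builds the
#' per-category tables and the operating-threshold diagnostic metrics,
#' and returns them as one comparison object (printable as text tables,
#' serialisable as JSON via [comparison_json()]).
#'
#' @param cohort Validated cohort data.frame with pathology labels.
#' @param systems Systems to evaluate (default all five).
#' @param ... Passed to [tirads_classify()].
#' @return Object of class `tirads_comparison`: list with `tables` (named
#'   list of category tables), `metrics` (one row per system), and
#'   `notes` (known caveats attached to specific cells).
#' @export
compare_systems <- function(cohort, systems = tirads_systems(), ...) {
  systems <- match.arg(systems, tirads_systems(), several.ok = TRUE)
  tables <- sapply(systems, function(s) category_table(cohort, s, ...),
                   simplify = FALSE)
  comparison_from_tables(tables)
}

#' Comparison object from pre-built category tables
#'
#' Same output as [compare_systems()] but starting from per-category
#' counts (e.g. a published contingency fixture) instead of per-nodule
#' records.
#'
#' @param tables Named list of category tables.
#' @return `tirads_comparison` object.
#' @export
comparison_from_tables <- function(tables) {
  metrics <- do.call(rbind, lapply(names(tables), function(s) {
    cbind(data.frame(system = s, stringsAsFactors = FALSE),
          diagnostic_metrics(confusion(tables[[s]])))
  }))
  rownames(metrics) <- NULL
  structure(list(tables = tables, metrics = metrics,
                 notes = comparison_notes(names(tables))),
            class = "tirads_comparison")
}

# Cell-level caveats surfaced in reports rather than force-matched.
comparison_notes <- function(systems) {
  notes <- character()
  if ("acr" %in% systems) {
    notes <- c(notes, paste(
      "ACR specificity and PPV as originally reported for this design are",
      "not reconstructible from its per-category counts; values here are",
      "computed from the counts."))
  }
  notes
}

#' @export
print.tirads_comparison <- function(x, ...) {
  for (s in names(x$tables)) {
    cat(render_category_table(x$tables[[s]]), sep = "\n")
    cat("\n")
  }
  cat(render_metrics_table(x$metrics), sep = "\n")
  if (length(x$notes)) cat("\nNotes:\n", paste("-", x$notes, collapse = "\n"),
                           "\n", sep = "")
  invisible(x)
}

#' Serialise a comparison as JSON
#'
#' @param x `tirads_comparison` object.
#' @param ... Passed to [jsonlite::toJSON()].
#' @return JSON string.
#' @export
comparison_json <- function(x, ...) {
  jsonlite::toJSON(list(tables = x$tables, metrics = x$metrics,
                        notes = x$notes),
                   dataframe = "rows", na = "null", auto_unbox = TRUE,
                   digits = NA, ...)
}
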