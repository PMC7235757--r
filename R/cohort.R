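# Nodule feature schema, validation and cohort CSV I/O.
#
# A cohort is a plain data.frame with one row per nodule.  Enumerated
# features are lowercase snake_case tokens, booleans are logical (0/1 in
# CSV), the echogenic-foci set is encoded as four 0/1 columns so that
# several foci types can co-occur (the ACR score sums over all present).

#' Vocabulary of the nodule feature schema
#'
#' Allowed values for each enumerated column of a nodule cohort.
#'
#' @return Named list of character vectors, one per enumerated column.
#' @export
cohort_vocabulary <- function() {
  list(
    composition  = c("solid", "mixed", "spongiform", "cystic"),
    echogenicity = c("hyperechoic", "isoechoic", "mild_hypoechoic",
                     "marked_hypoechoic", "anechoic"),
    margins      = c("smooth", "blurred_ill_defined", "irregular",
                     "extrathyroidal_extension"),
    capsule_2d   = c("nonencapsulated", "thin", "thick"),
    vasc_2d      = c("none", "peripheral", "internal", "penetrating",
                     "hypervascular"),
    pathology    = c("benign", "malignant")
  )
}

# Column classes of a cohort data.frame, in canonical order.
cohort_columns <- function() {
  c(id = "character",
    composition = "character", echogenicity = "character",
    taller_than_wide = "logical", margins = "character",
    foci_comet_tail = "logical", foci_macrocalcification = "logical",
    foci_rim_calcification = "logical", foci_microcalcification = "logical",
    capsule_2d = "character", vasc_2d = "character",
    background_hashimoto = "logical", colloid_pattern = "logical",
    strain_ratio = "numeric", asteria_score = "integer",
    d3_capsule_altered = "logical", d3_intranodular_increased = "logical",
    suspicious_lymph_nodes = "logical",
    max_diameter_mm = "numeric", pathology = "character")
}

# Columns that may contain missing values.
cohort_optional_columns <- function() {
  c("strain_ratio", "asteria_score", "max_diameter_mm", "pathology")
}

#' Validate a nodule cohort
#'
#' Checks a cohort data.frame against the feature schema: all mandatory
#' columns present, enumeration values in vocabulary, strain ratio finite
#' and non-negative, Asteria score in 1..4, anechoic echogenicity only in
#' cystic or mixed nodules.  Completely cystic nodules are valid records
#' but are flagged out-of-study (the systems compared here were evaluated
#' on solid and mixed nodules only).
#'
#' @param cohort data.frame with one row per nodule.
#' @return Invisibly, `cohort` with a logical `out_of_study` column added
#'   and row-level problems (if any) in attribute `"problems"`, a
#'   data.frame with columns `row`, `column`, `message`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  cols <- cohort_columns()
  missing_cols <- setdiff(names(cols), names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vocab <- cohort_vocabulary()
  problems <- list()
  flag <- function(rows, column, message) {
    if (any(rows)) {
      problems[[length(problems) + 1L]] <<-
        data.frame(row = which(rows), column = column, message = message,
                   stringsAsFactors = FALSE)
    }
  }
  for (col in names(vocab)) {
    x <- cohort[[col]]
    allow_na <- col %in% cohort_optional_columns()
    bad <- !(x %in% vocab[[col]]) & !(allow_na & is.na(x))
    flag(bad, col, paste0("value not in {", paste(vocab[[col]], collapse = ", "), "}"))
  }
  for (col in names(cols)[cols == "logical"]) {
    flag(is.na(cohort[[col]]), col, "boolean field may not be missing")
  }
  sr <- cohort$strain_ratio
  flag(!is.na(sr) & (!is.finite(sr) | sr < 0), "strain_ratio",
       "must be finite and >= 0")
  ast <- cohort$asteria_score
  flag(!is.na(ast) & !(ast %in% 1:4), "asteria_score", "must be in 1..4")
  flag(!is.na(cohort$max_diameter_mm) & cohort$max_diameter_mm <= 0,
       "max_diameter_mm", "must be positive")
  flag(cohort$echogenicity %in% "anechoic" &
         !(cohort$composition %in% c("cystic", "mixed")),
       "echogenicity", "anechoic requires cystic or mixed composition")
  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(), column = character(), message = character(),
               stringsAsFactors = FALSE)
  cohort$out_of_study <- cohort$composition %in% "cystic"
  attr(cohort, "problems") <- problems[order(problems$row), , drop = FALSE]
  invisible(cohort)
}

#' Read a nodule cohort from CSV
#'
#' Reads a comma-separated, UTF-8, headered cohort file (booleans 0/1,
#' enums as lowercase tokens, missing values empty).  Rows violating the
#' schema are dropped; the parse report is attached as attribute
#' `"parse_report"` listing each skipped row and why.
#'
#' @param path Path to the CSV file.
#' @param drop_invalid Drop rows with validation problems (default TRUE).
#' @return data.frame of validated nodule records, row order preserved,
#'   with `out_of_study` flag and attributes `parse_report` (data.frame of
#'   skipped rows) and `n_skipped`.
#' @export
read_cohort <- function(path, drop_invalid = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cols <- cohort_columns()
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  missing_cols <- setdiff(names(cols), names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw[names(cols)]
  for (col in names(cols)) {
    x <- out[[col]]
    x[x == ""] <- NA_character_
    out[[col]] <- switch(
      cols[[col]],
      character = x,
      logical   = x %in% "1" | (is.na(x) & NA),
      numeric   = suppressWarnings(as.numeric(x)),
      integer   = suppressWarnings(as.integer(x))
    )
    if (cols[[col]] == "logical") {
      bad <- !(raw[[col]] %in% c("0", "1"))
      out[[col]][bad] <- NA
    }
  }
  out <- validate_cohort(out)
  problems <- attr(out, "problems")
  if (drop_invalid && nrow(problems) > 0L) {
    keep <- !(seq_len(nrow(out)) %in% problems$row)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "problems") <- NULL
  attr(out, "parse_report") <- problems
  attr(out, "n_skipped") <- length(unique(problems$row))
  out
}

#' Write a nodule cohort to CSV
#'
#' Inverse of [read_cohort()]: booleans as 0/1, missing values as empty
#' fields, canonical column order.  `write_cohort(read_cohort(f))`
#' round-trips all field values exactly for valid files.
#'
#' @param cohort Validated cohort data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- cohort_columns()
  out <- cohort[names(cols)]
  for (col in names(cols)[cols == "logical"]) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Elastographic stiffness positivity (strain ratio cutoff)
#'
#' A nodule is stiff, hence elastography-positive, when its
#' parenchyma-to-nodule strain ratio strictly exceeds the cutoff
#' (default 4, the operating cutoff established for the strain
#' elastography equipment class modelled here).
#'
#' @param cohort Cohort data.frame.
#' @param cutoff Strain-ratio cutoff; positivity is `strain_ratio > cutoff`.
#' @return Logical vector; `NA` where the strain ratio is unavailable
#'   (never silently imputed — callers decide how to treat the gap).
#' @export
stiffness_positive <- function(cohort, cutoff = 4) {
  cohort$strain_ratio > cutoff
}

#' Volumetric (4D) Color Doppler positivity
#'
#' Positive when the 3D/4D Doppler acquisition shows an interrupted
#' thyroid capsule or increased intranodular vascularization (disjunctive
#' criterion).
#'
#' @param cohort Cohort data.frame.
#' @return Logical vector.
#' @export
doppler4d_positive <- function(cohort) {
  cohort$d3_capsule_altered | cohort$d3_intranodular_increased
}

# TRUE where the foci set contains the given focus type.
has_focus <- function(cohort, focus) {
  cohort[[paste0("foci_", focus)]]
}
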