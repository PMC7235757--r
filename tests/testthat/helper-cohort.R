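# Fixture builders: a single prototypical nodule with overridable fields,
# and a randomized valid-record generator spanning the whole schema
# vocabulary (for property-style tests).

make_nodule <- function(...) {
  base <- data.frame(
    id = "N1", composition = "solid", echogenicity = "isoechoic",
    taller_than_wide = FALSE, margins = "smooth",
    foci_comet_tail = FALSE, foci_macrocalcification = FALSE,
    foci_rim_calcification = FALSE, foci_microcalcification = FALSE,
    capsule_2d = "nonencapsulated", vasc_2d = "none",
    background_hashimoto = FALSE, colloid_pattern = FALSE,
    strain_ratio = 2, asteria_score = 1L,
    d3_capsule_altered = FALSE, d3_intranodular_increased = FALSE,
    suspicious_lymph_nodes = FALSE, max_diameter_mm = 15,
    pathology = "benign", stringsAsFactors = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

make_cohort <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# Random valid records over the full vocabulary (anechoic only for
# cystic/mixed composition, per the schema invariant).
random_cohort <- function(n, seed = NULL, with_pathology = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  vocab <- cohort_vocabulary()
  composition <- sample(vocab$composition, n, replace = TRUE)
  echogenicity <- vapply(composition, function(comp) {
    pool <- vocab$echogenicity
    if (!comp %in% c("cystic", "mixed")) pool <- setdiff(pool, "anechoic")
    sample(pool, 1)
  }, character(1))
  data.frame(
    id = sprintf("R%05d", seq_len(n)),
    composition = composition, echogenicity = echogenicity,
    taller_than_wide = sample(c(TRUE, FALSE), n, replace = TRUE),
    margins = sample(vocab$margins, n, replace = TRUE),
    foci_comet_tail = sample(c(TRUE, FALSE), n, TRUE, prob = c(.15, .85)),
    foci_macrocalcification = sample(c(TRUE, FALSE), n, TRUE, prob = c(.2, .8)),
    foci_rim_calcification = sample(c(TRUE, FALSE), n, TRUE, prob = c(.1, .9)),
    foci_microcalcification = sample(c(TRUE, FALSE), n, TRUE, prob = c(.3, .7)),
    capsule_2d = sample(vocab$capsule_2d, n, replace = TRUE),
    vasc_2d = sample(vocab$vasc_2d, n, replace = TRUE),
    background_hashimoto = sample(c(TRUE, FALSE), n, TRUE, prob = c(.1, .9)),
    colloid_pattern = sample(c(TRUE, FALSE), n, TRUE, prob = c(.15, .85)),
    strain_ratio = round(stats::rlnorm(n, 1, 0.7), 3),
    asteria_score = sample(1:4, n, replace = TRUE),
    d3_capsule_altered = sample(c(TRUE, FALSE), n, TRUE, prob = c(.2, .8)),
    d3_intranodular_increased = sample(c(TRUE, FALSE), n, TRUE, prob = c(.25, .75)),
    suspicious_lymph_nodes = sample(c(TRUE, FALSE), n, TRUE, prob = c(.1, .9)),
    max_diameter_mm = round(stats::runif(n, 5, 40), 1),
    pathology = if (with_pathology)
      sample(c("benign", "malignant"), n, TRUE, prob = c(.7, .3))
    else NA_character_,
    stringsAsFactors = FALSE
  )
}

counts_fixture <- function() {
  read_counts(system.file("extdata", "category_counts.csv",
                          package = "tiradsx", mustWork = TRUE))
}
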