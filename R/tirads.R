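# Rule engines for the five TI-RADS risk-stratification systems.
#
# Every classifier is vectorised over the rows of a validated cohort and
# returns a character vector of category labels on that system's scale.
# Ordinal comparisons between categories go through category_rank(), which
# puts all systems on a common 1..6 integer scale (1,2,3 -> 1,2,3; 4 and
# 4A -> 4; 4B -> 5; 5 -> 6).

#' Supported risk-stratification systems
#' @return Character vector of system identifiers.
#' @export
tirads_systems <- function() c("eu", "acr", "horvath", "french", "french4d")

#' Category scale of a system
#'
#' The categories a nodule can actually receive: category 1 means "no
#' nodules" in EU, Horvath and French TI-RADS and is therefore only
#' assignable under ACR (where it is the 0–1 point band).
#'
#' @param system One of [tirads_systems()].
#' @return Character vector of assignable category labels, lowest risk first.
#' @export
system_scale <- function(system) {
  system <- match.arg(system, tirads_systems())
  switch(system,
         eu  = c("2", "3", "4", "5"),
         acr = c("1", "2", "3", "4", "5"),
         c("2", "3", "4A", "4B", "5"))
}

#' Common ordinal rank of category labels
#'
#' @param label Character vector of category labels.
#' @return Integer rank: 1,2,3 -> 1,2,3; 4 or 4A -> 4; 4B -> 5; 5 -> 6.
#' @export
category_rank <- function(label) {
  ranks <- c("1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L, "4A" = 4L,
             "4B" = 5L, "5" = 6L)
  out <- unname(ranks[as.character(label)])
  if (anyNA(out) && !anyNA(label)) {
    stop("unknown category label(s): ",
         paste(unique(label[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' EU-TIRADS classification
#'
#' Benign (2) for cystic or spongiform nodules; high suspicion (5) when at
#' least one suspicious feature is present (non-oval/taller-than-wide
#' shape, irregular margins or extrathyroidal extension,
#' microcalcifications, marked hypoechogenicity); intermediate (4) for
#' mildly hypoechoic nodules without suspicious features; low (3) for
#' iso-/hyperechoic nodules without suspicious features.
#'
#' @param cohort Validated cohort data.frame.
#' @return Character vector of categories in `{"2","3","4","5"}`.
#' @export
classify_eu <- function(cohort) {
  contradictory <- cohort$echogenicity == "anechoic" &
    cohort$composition == "solid"
  if (any(contradictory)) {
    stop("anechoic solid nodule(s): ",
         paste(cohort$id[contradictory], collapse = ", "), call. = FALSE)
  }
  suspicious <- cohort$taller_than_wide |
    cohort$margins %in% c("irregular", "extrathyroidal_extension") |
    has_focus(cohort, "microcalcification") |
    cohort$echogenicity == "marked_hypoechoic"
  ifelse(cohort$composition %in% c("cystic", "spongiform"), "2",
  ifelse(suspicious, "5",
  ifelse(cohort$echogenicity == "mild_hypoechoic", "4", "3")))
}

#' Default ACR TI-RADS point values
#'
#' Published per-feature points of the cumulative ACR score over its five
#' ultrasound categories (composition, echogenicity, shape, margins,
#' echogenic foci); foci points are summed over all foci present.
#' Values can be overridden (e.g. from a YAML config) by passing a
#' modified copy to [score_acr()].
#'
#' @return Named list of point assignments.
#' @export
acr_points <- function() {
  list(
    composition  = c(cystic = 0, spongiform = 0, mixed = 1, solid = 2),
    echogenicity = c(anechoic = 0, hyperechoic = 1, isoechoic = 1,
                     mild_hypoechoic = 2, marked_hypoechoic = 3),
    shape_taller = 3,
    margins      = c(smooth = 0, blurred_ill_defined = 0, irregular = 2,
                     extrathyroidal_extension = 3),
    foci         = c(comet_tail = 0, macrocalcification = 1,
                     rim_calcification = 2, microcalcification = 3)
  )
}

#' ACR TI-RADS cumulative score
#'
#' @param cohort Validated cohort data.frame.
#' @param points Point configuration, see [acr_points()].
#' @return data.frame with the five per-category point components and the
#'   cumulative `total`.
#' @export
score_acr <- function(cohort, points = acr_points()) {
  foci <- points$foci
  pts <- data.frame(
    points_composition  = unname(points$composition[cohort$composition]),
    points_echogenicity = unname(points$echogenicity[cohort$echogenicity]),
    points_shape        = ifelse(cohort$taller_than_wide, points$shape_taller, 0),
    points_margin       = unname(points$margins[cohort$margins]),
    points_foci         = has_focus(cohort, "comet_tail") * foci[["comet_tail"]] +
      has_focus(cohort, "macrocalcification") * foci[["macrocalcification"]] +
      has_focus(cohort, "rim_calcification") * foci[["rim_calcification"]] +
      has_focus(cohort, "microcalcification") * foci[["microcalcification"]]
  )
  pts$total <- rowSums(pts)
  pts
}

#' ACR TI-RADS classification
#'
#' Maps the cumulative score to the published bands: 0–1 points -> TR1,
#' 2 -> TR2, 3 -> TR3, 4–6 -> TR4, 7 or more -> TR5.  (A total of 1 is
#' not mapped by the published bands; it is conservatively assigned TR1.)
#'
#' @inheritParams score_acr
#' @return Character vector of categories in `{"1","2","3","4","5"}`.
#' @export
classify_acr <- function(cohort, points = acr_points()) {
  total <- score_acr(cohort, points)$total
  ifelse(total <= 1, "1",
  ifelse(total == 2, "2",
  ifelse(total == 3, "3",
  ifelse(total <= 6, "4", "5"))))
}

#' Horvath TI-RADS classification
#'
#' Pattern-based classification; patterns are evaluated from category 5
#' downwards and the first (highest-risk) matching pattern wins:
#' * 5: iso-/hypoechoic nonencapsulated hypervascular nodule with
#'   microcalcifications, or a nonencapsulated isoechoic mixed
#'   hypervascular nodule;
#' * 4B: hypoechoic nodule with irregular margins or taller-than-wide
#'   shape and penetrating or hypervascular 2D Doppler pattern;
#' * 4A: thin-capsule nodule of any echogenicity, a hypoechoic nodule
#'   with blurred margins and no calcifications, or a hypervascular
#'   thick-capsule nodule with calcifications;
#' * 3: Hashimoto pseudo-nodule;
#' * 2: colloid or spongiform nodule, or mixed isoechoic nodule.
#' Unmatched solid nodules fall back to 4A — the published pattern list is
#' not exhaustive; the fallback count is attached as attribute
#' `"n_fallback"` so its frequency stays visible.
#'
#' @param cohort Validated cohort data.frame.
#' @return Character vector of categories in `{"2","3","4A","4B","5"}`,
#'   with attribute `n_fallback`.
#' @export
classify_horvath <- function(cohort) {
  hypo <- cohort$echogenicity %in% c("mild_hypoechoic", "marked_hypoechoic")
  iso_or_hypo <- hypo | cohort$echogenicity == "isoechoic"
  calcified <- has_focus(cohort, "microcalcification") |
    has_focus(cohort, "macrocalcification") |
    has_focus(cohort, "rim_calcification")
  hypervasc <- cohort$vasc_2d == "hypervascular"

  p5 <- (iso_or_hypo & cohort$capsule_2d == "nonencapsulated" &
           has_focus(cohort, "microcalcification") & hypervasc) |
    (cohort$capsule_2d == "nonencapsulated" &
       cohort$echogenicity == "isoechoic" &
       cohort$composition == "mixed" & hypervasc)
  p4b <- hypo &
    (cohort$margins %in% c("irregular", "extrathyroidal_extension") |
       cohort$taller_than_wide) &
    cohort$vasc_2d %in% c("penetrating", "hypervascular")
  p4a <- cohort$capsule_2d == "thin" |
    (hypo & cohort$margins == "blurred_ill_defined" & !calcified) |
    (hypervasc & cohort$capsule_2d == "thick" & calcified)
  p3 <- cohort$background_hashimoto
  p2 <- cohort$colloid_pattern | cohort$composition == "spongiform" |
    (cohort$composition == "mixed" & cohort$echogenicity == "isoechoic")

  out <- ifelse(p5, "5",
         ifelse(p4b, "4B",
         ifelse(p4a, "4A",
         ifelse(p3, "3",
         ifelse(p2, "2", "4A")))))
  attr(out, "n_fallback") <- sum(!p5 & !p4b & !p4a & !p3 & !p2)
  out
}

#' Count French TI-RADS high-suspicion features
#'
#' The five French suspicion features are taller-than-wide shape,
#' irregular margins (including extrathyroidal extension; blurred margins
#' do not count), marked hypoechogenicity, microcalcifications, and
#' elastographic stiffness (strain ratio > cutoff).  With `include_4d`,
#' 4D Doppler positivity (interrupted capsule or increased intranodular
#' vascularity) is counted as a sixth feature.
#'
#' A missing strain ratio is counted as feature absent, with a warning:
#' stiffness is never imputed.
#'
#' @param cohort Validated cohort data.frame.
#' @param include_4d Count 4D Doppler positivity as an extra feature.
#' @param sr_cutoff Strain-ratio stiffness cutoff (default 4).
#' @return data.frame of per-feature logicals plus the feature `count`.
#' @export
count_suspicion <- function(cohort, include_4d = FALSE, sr_cutoff = 4) {
  stiff <- stiffness_positive(cohort, sr_cutoff)
  if (anyNA(stiff)) {
    warning("strain ratio unavailable for ", sum(is.na(stiff)),
            " nodule(s); stiffness counted as absent", call. = FALSE)
    stiff[is.na(stiff)] <- FALSE
  }
  feats <- data.frame(
    taller_than_wide   = cohort$taller_than_wide,
    irregular_margins  = cohort$margins %in% c("irregular",
                                               "extrathyroidal_extension"),
    marked_hypoechoic  = cohort$echogenicity == "marked_hypoechoic",
    microcalcifications = has_focus(cohort, "microcalcification"),
    stiff_elastography = stiff
  )
  if (include_4d) feats$doppler4d <- doppler4d_positive(cohort)
  feats$count <- as.integer(rowSums(feats))
  feats
}

#' French TI-RADS classification (with optional 4D Doppler feature)
#'
#' Benign (2) for cystic or spongiform nodules and for isolated
#' macrocalcifications (macrocalcification as the only focus type and no
#' suspicion feature); high suspicion (5) for suspicious lymph nodes or
#' three or more suspicion features; 4B for one or two features; 4A for
#' mildly hypoechoic nodules without features; otherwise 3 (oval, regular
#' margins, iso-/hyperechoic).
#'
#' `include_4d = TRUE` selects the 4D-Doppler-augmented variant: Doppler
#' positivity is an additional suspicion feature, so the 4D variant can
#' only upgrade, never downgrade, the classic French category.
#'
#' @inheritParams count_suspicion
#' @return Character vector of categories in `{"2","3","4A","4B","5"}`.
#' @export
classify_french <- function(cohort, include_4d = FALSE, sr_cutoff = 4) {
  feats <- count_suspicion(cohort, include_4d = include_4d,
                           sr_cutoff = sr_cutoff)
  isolated_macro <- has_focus(cohort, "macrocalcification") &
    !has_focus(cohort, "microcalcification") &
    !has_focus(cohort, "rim_calcification") &
    !has_focus(cohort, "comet_tail") &
    feats$count == 0L
  ifelse(cohort$composition %in% c("cystic", "spongiform") | isolated_macro, "2",
  ifelse(cohort$suspicious_lymph_nodes | feats$count >= 3L, "5",
  ifelse(feats$count >= 1L, "4B",
  ifelse(cohort$echogenicity == "mild_hypoechoic", "4A", "3"))))
}

#' Classify a cohort under any supported system
#'
#' @param cohort Validated cohort data.frame.
#' @param system One of [tirads_systems()].
#' @param ... Passed to the system's classifier (e.g. `points` for ACR,
#'   `sr_cutoff` for the French variants).
#' @return Character vector of category labels.
#' @export
tirads_classify <- function(cohort, system, ...) {
  system <- match.arg(system, tirads_systems())
  switch(system,
         eu       = classify_eu(cohort),
         acr      = classify_acr(cohort, ...),
         horvath  = classify_horvath(cohort),
         french   = classify_french(cohort, include_4d = FALSE, ...),
         french4d = classify_french(cohort, include_4d = TRUE, ...))
}

#' Operating thresholds of the binary test-positive call
#'
#' The category at and above which a system's call is test-positive:
#' category 4 for EU and ACR, category 4B for Horvath and both French
#' variants.  These are the operating points under which each system's
#' per-category counts reproduce its published diagnostic metrics.
#'
#' @return Named character vector of threshold categories per system.
#' @export
operating_thresholds <- function() {
  c(eu = "4", acr = "4", horvath = "4B", french = "4B", french4d = "4B")
}

#' Binary test-positive call from a risk category
#'
#' @param label Character vector of category labels.
#' @param system One of [tirads_systems()].
#' @param threshold Threshold category (default the system's operating
#'   threshold, see [operating_thresholds()]).
#' @return Logical vector: TRUE where the category is at or above the
#'   threshold on the common ordinal scale.
#' @export
binary_call <- function(label, system, threshold = NULL) {
  system <- match.arg(system, tirads_systems())
  if (is.null(threshold)) threshold <- operating_thresholds()[[system]]
  category_rank(label) >= category_rank(threshold)
}
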