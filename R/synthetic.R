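# Synthetic thyroid-nodule cohort generator.
#
# Emulates the study conditions of a surgical cohort of solid nodules:
# class-conditional Bernoulli feature prevalences, lognormal strain-ratio
# distributions pinned down by each class's mean and stiffness-exceedance
# fraction, and (optionally) a Gaussian-copula dependence structure over
# the core suspicion features.  Marginals not published for the source
# cohort are documented free defaults; they shape only the Horvath/ACR
# category mixes.

#' Solve lognormal strain-ratio parameters from mean and exceedance
#'
#' Finds `(meanlog, sdlog)` of the lognormal distribution with the given
#' arithmetic mean and exceedance probability `P(SR > cutoff)`.  Writing
#' `z = qnorm(1 - p)`, the two constraints reduce to the quadratic
#' `sdlog^2/2 - z*sdlog + log(cutoff/mean) = 0`; when both roots are
#' admissible the smaller (less skewed) one is taken.
#'
#' @param mean Arithmetic mean of the strain ratio.
#' @param exceedance Probability that the strain ratio exceeds `cutoff`.
#' @param cutoff Stiffness cutoff (default 4).
#' @return Named vector `c(meanlog, sdlog)`.
#' @export
sr_lognormal_params <- function(mean, exceedance, cutoff = 4) {
  stopifnot(mean > 0, exceedance > 0, exceedance < 1)
  z <- stats::qnorm(1 - exceedance)
  disc <- z^2 - 2 * log(cutoff / mean)
  if (disc < 0) {
    stop("no lognormal has mean ", mean, " and P(SR>", cutoff, ") = ",
         exceedance, call. = FALSE)
  }
  roots <- sort(c(z - sqrt(disc), z + sqrt(disc)))
  sdlog <- roots[roots > 0][1]
  if (is.na(sdlog)) stop("no positive sdlog root", call. = FALSE)
  c(meanlog = log(cutoff) - z * sdlog, sdlog = sdlog)
}

#' Default synthetic-cohort parameters
#'
#' The defaults reproduce the study conditions: 133 nodules at 26.31%
#' malignancy prevalence (35/133); class-conditional prevalences of
#' blurred margins (28.57%/37%), microcalcification (9.1%/31.4%), marked
#' hypoechogenicity (3.06%/25.7%), taller-than-wide shape (15.3%/42.8%)
#' and 4D Doppler positivity (14.28%/65%); lognormal strain-ratio
#' parameters solved so that the class means are 2.54 (benign) and 5.56
#' (malignant) with stiffness exceedances P(SR>4) of 12.24% and 80%; and
#' suspicious-lymph-node probabilities giving an expected 13 node-positive
#' cases per 133 nodules.  Remaining marginals (mild hypoechogenicity,
#' 2D vascular pattern, capsule type, Hashimoto/colloid/spongiform rates,
#' non-micro foci) are free defaults chosen as plausible for a surgical
#' solid-nodule series; see the package vignette.
#'
#' @return A `cohort_params` list: `n`, `prevalence`, `probs`
#'   (feature-by-class Bernoulli probabilities), `sr` (per-class lognormal
#'   parameters), `doppler_split` (vascularity-only / capsule-only / both
#'   split of a positive 4D call), `iso_share` (isoechoic share of
#'   non-hypoechoic nodules), `vasc_weights` (2D Doppler pattern weights
#'   for non-hypervascular nodules), and `corr` (optional copula
#'   correlation matrix, `NULL` = class-conditional independence).
#' @export
default_cohort_params <- function() {
  probs <- rbind(
    irregular_margins      = c(0.05,   0.35),
    blurred_margins        = c(0.2857, 0.37),
    microcalcification     = c(0.091,  0.314),
    marked_hypoechoic      = c(0.0306, 0.257),
    taller_than_wide       = c(0.153,  0.428),
    doppler4d              = c(0.1428, 0.65),
    suspicious_lymph_nodes = c(0.025,  0.30),
    mild_hypoechoic        = c(0.45,   0.40),
    hashimoto              = c(0.08,   0.03),
    colloid                = c(0.15,   0.00),
    spongiform             = c(0.05,   0.00),
    hypervascular_2d       = c(0.10,   0.30),
    thin_capsule           = c(0.20,   0.10),
    thick_capsule          = c(0.10,   0.10),
    macrocalcification     = c(0.15,   0.10),
    comet_tail             = c(0.10,   0.02),
    rim_calcification      = c(0.03,   0.05)
  )
  colnames(probs) <- c("benign", "malignant")
  structure(list(
    n = 133L,
    prevalence = 35 / 133,
    probs = probs,
    sr = list(benign = sr_lognormal_params(2.54, 0.1224),
              malignant = sr_lognormal_params(5.56, 0.80)),
    doppler_split = c(vascularity_only = 0.50, capsule_only = 0.35,
                      both = 0.15),
    iso_share = 0.8,
    vasc_weights = c(none = 0.35, peripheral = 0.40, internal = 0.20,
                     penetrating = 0.05),
    corr = NULL
  ), class = "cohort_params")
}

# Variables that the copula (when supplied) may couple, in latent order.
copula_variables <- function() {
  c("taller_than_wide", "marked_hypoechoic", "microcalcification",
    "irregular_margins", "blurred_margins", "doppler4d",
    "suspicious_lymph_nodes", "strain_ratio")
}

# Project a symmetric matrix onto the nearest (eigenvalue-clipped)
# positive semidefinite correlation matrix.
project_correlation <- function(m) {
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    stop("copula correlation matrix must be symmetric", call. = FALSE)
  }
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) >= -1e-10) return(m)
  v <- pmax(e$values, 1e-8)
  out <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  if (min(eigen(out, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("projection of the copula correlation matrix to positive ",
         "semidefinite failed", call. = FALSE)
  }
  out
}

# Latent-uniform draws: independent, or Gaussian-copula coupled for the
# variables named in corr.  Returns an n x length(vars) matrix of U(0,1)
# margins.
latent_uniforms <- function(n, vars, corr) {
  u <- matrix(stats::runif(n * length(vars)), nrow = n,
              ncol = length(vars), dimnames = list(NULL, vars))
  if (is.null(corr) || n == 0L) return(u)
  cv <- colnames(corr)
  if (is.null(cv) || !all(cv %in% vars)) {
    stop("copula correlation matrix must have dimnames drawn from: ",
         paste(copula_variables(), collapse = ", "), call. = FALSE)
  }
  r <- project_correlation(corr)
  z <- matrix(stats::rnorm(n * ncol(r)), nrow = n) %*%
    chol(r, pivot = FALSE)
  u[, cv] <- stats::pnorm(z)
  u
}

#' Generate a synthetic nodule cohort
#'
#' Draws `n` nodules: pathology Bernoulli(prevalence), features from the
#' class-conditional model, continuous strain ratio from the class
#' lognormal.  The binary stiffness feature used downstream is always
#' derived from the drawn strain ratio (never drawn separately), and the
#' Asteria score is the cohort strain-ratio quartile (1 = softest
#' quartile, 4 = stiffest).  Irregular and blurred margins are mutually
#' exclusive, irregular drawn first (the blurred draw probability is
#' inflated so the blurred *marginal* matches its target).  Composition is
#' solid unless the spongiform or colloid flags fire (colloid nodules are
#' generated mixed isoechoic).  A positive 4D Doppler call is split into
#' vascularity-only / capsule-only / both per `doppler_split`.
#'
#' @param params `cohort_params` list, see [default_cohort_params()].
#' @param n Cohort size override.
#' @param seed Integer seed; the same seed yields an identical cohort.
#' @return Validated cohort data.frame of `n` records.
#' @export
generate_cohort <- function(params = default_cohort_params(), n = params$n,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(params$probs >= 0 & params$probs <= 1),
            params$prevalence >= 0, params$prevalence <= 1)
  malignant <- stats::runif(n) < params$prevalence
  cls <- ifelse(malignant, "malignant", "benign")
  p <- function(feature) params$probs[feature, ][cls]

  # binary features fire on the UPPER tail of their latent uniform so a
  # positive copula correlation induces positive association with the
  # (increasing) strain-ratio transform
  u <- latent_uniforms(n, copula_variables(), params$corr)
  fire <- function(var, prob) u[, var] > 1 - prob
  taller <- fire("taller_than_wide", p("taller_than_wide"))
  marked <- fire("marked_hypoechoic", p("marked_hypoechoic"))
  micro  <- fire("microcalcification", p("microcalcification"))
  irregular <- fire("irregular_margins", p("irregular_margins"))
  # inflate so the observed blurred marginal hits its target despite the
  # exclusivity with irregular margins
  p_blur <- pmin(1, p("blurred_margins") / (1 - p("irregular_margins")))
  blurred <- !irregular & fire("blurred_margins", p_blur)
  d4 <- fire("doppler4d", p("doppler4d"))
  lymph <- fire("suspicious_lymph_nodes", p("suspicious_lymph_nodes"))
  srp <- params$sr
  sr <- stats::qlnorm(u[, "strain_ratio"],
                      meanlog = ifelse(malignant, srp$malignant[["meanlog"]],
                                       srp$benign[["meanlog"]]),
                      sdlog = ifelse(malignant, srp$malignant[["sdlog"]],
                                     srp$benign[["sdlog"]]))

  hashimoto <- stats::runif(n) < p("hashimoto")
  colloid <- stats::runif(n) < p("colloid")
  spongiform <- stats::runif(n) < p("spongiform")
  hypervasc <- stats::runif(n) < p("hypervascular_2d")
  thin <- stats::runif(n) < p("thin_capsule")
  thick <- !thin & stats::runif(n) < p("thick_capsule")
  macro <- stats::runif(n) < p("macrocalcification")
  comet <- stats::runif(n) < p("comet_tail")
  rim <- stats::runif(n) < p("rim_calcification")

  composition <- ifelse(spongiform, "spongiform",
                 ifelse(colloid, "mixed", "solid"))
  mild <- !marked & stats::runif(n) < p("mild_hypoechoic")
  iso <- !marked & !mild &
    (colloid | stats::runif(n) < params$iso_share)
  echogenicity <- ifelse(marked, "marked_hypoechoic",
                  ifelse(mild, "mild_hypoechoic",
                  ifelse(iso, "isoechoic", "hyperechoic")))
  margins <- ifelse(irregular, "irregular",
             ifelse(blurred, "blurred_ill_defined", "smooth"))
  vw <- params$vasc_weights / sum(params$vasc_weights)
  vasc <- ifelse(hypervasc, "hypervascular",
                 names(vw)[1L + findInterval(stats::runif(n),
                                             cumsum(vw)[-length(vw)])])
  capsule <- ifelse(thin, "thin", ifelse(thick, "thick", "nonencapsulated"))
  ds <- params$doppler_split / sum(params$doppler_split)
  mode <- names(ds)[1L + findInterval(stats::runif(n),
                                      cumsum(ds)[-length(ds)])]
  d3_intra <- d4 & mode %in% c("vascularity_only", "both")
  d3_caps <- d4 & mode %in% c("capsule_only", "both")

  asteria <- if (n > 0) {
    qs <- stats::quantile(sr, probs = 0:4 / 4, names = FALSE)
    as.integer(cut(sr, breaks = unique(qs), include.lowest = TRUE,
                   labels = FALSE))
  } else integer(0)
  cohort <- data.frame(
    id = sprintf("SYN%05d", seq_len(n)),
    composition = composition, echogenicity = echogenicity,
    taller_than_wide = taller, margins = margins,
    foci_comet_tail = comet, foci_macrocalcification = macro,
    foci_rim_calcification = rim, foci_microcalcification = micro,
    capsule_2d = capsule, vasc_2d = vasc,
    background_hashimoto = hashimoto, colloid_pattern = colloid,
    strain_ratio = sr, asteria_score = asteria,
    d3_capsule_altered = d3_caps, d3_intranodular_increased = d3_intra,
    suspicious_lymph_nodes = lymph,
    max_diameter_mm = rep(NA_real_, n),
    pathology = cls,
    stringsAsFactors = FALSE
  )
  out <- validate_cohort(cohort)
  stopifnot(nrow(attr(out, "problems")) == 0L)
  attr(out, "problems") <- NULL
  out
}

#' Class-conditional feature prevalence summary
#'
#' Tallies, per pathology class, the six suspicion-feature prevalences
#' tracked by the generator defaults (blurred margins,
#' microcalcification, marked hypoechogenicity, taller-than-wide,
#' stiffness SR > 4, 4D Doppler positivity), plus the per-class mean
#' strain ratio as an attribute.
#'
#' @param cohort Validated cohort data.frame with pathology labels.
#' @param sr_cutoff Stiffness cutoff for the SR exceedance row.
#' @return data.frame `(feature, benign_count, benign_frac,
#'   malignant_count, malignant_frac)` with attribute `sr_mean` (named
#'   vector of class means).
#' @export
feature_prevalence <- function(cohort, sr_cutoff = 4) {
  feats <- list(
    blurred_margins = cohort$margins == "blurred_ill_defined",
    microcalcification = has_focus(cohort, "microcalcification"),
    marked_hypoechoic = cohort$echogenicity == "marked_hypoechoic",
    taller_than_wide = cohort$taller_than_wide,
    sr_exceeds_cutoff = stiffness_positive(cohort, sr_cutoff) %in% TRUE,
    doppler4d = doppler4d_positive(cohort)
  )
  ben <- cohort$pathology %in% "benign"
  mal <- cohort$pathology %in% "malignant"
  out <- data.frame(
    feature = names(feats),
    benign_count = vapply(feats, function(f) sum(f & ben), integer(1)),
    benign_frac = vapply(feats, function(f)
      if (sum(ben)) sum(f & ben) / sum(ben) else NA_real_, numeric(1)),
    malignant_count = vapply(feats, function(f) sum(f & mal), integer(1)),
    malignant_frac = vapply(feats, function(f)
      if (sum(mal)) sum(f & mal) / sum(mal) else NA_real_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "sr_mean") <- c(
    benign = if (sum(ben)) mean(cohort$strain_ratio[ben]) else NA_real_,
    malignant = if (sum(mal)) mean(cohort$strain_ratio[mal]) else NA_real_)
  out
}
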