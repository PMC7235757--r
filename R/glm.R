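# Binomial logistic regression by Fisher scoring (IRLS), with deviance,
# AIC, Wald inference and model comparison, plus the predictor coding and
# correlation matrix used for the cohort analysis.
#
# The fitter is implemented here from first principles; stats::glm serves
# only as an independent cross-check in the test suite.

#' Numeric design matrix for the cohort predictor analysis
#'
#' Codes cohort features for regression and correlation analysis: binary
#' features as 0/1, the strain ratio as continuous, TI-RADS categories as
#' their common ordinal rank (2..6, see [category_rank()]), and pathology
#' as the 0/1 response (malignant = 1).
#'
#' Recognised predictor names: `taller_than_wide`, `marked_hypoechoic`,
#' `microcalcification`, `irregular_margins`, `blurred_margins`,
#' `doppler4d`, `suspicious_lymph_nodes`, `strain_ratio`, and
#' `<system>_tirads` for any of [tirads_systems()].
#'
#' @param cohort Validated cohort data.frame with pathology labels.
#' @param predictors Character vector of predictor names.
#' @return List of class `tirads_design`: `x` (numeric matrix, one named
#'   column per predictor, no intercept), `y` (0/1 response), `n`.
#' @export
design_matrix <- function(cohort, predictors) {
  if (anyNA(cohort$pathology)) {
    stop("pathology label missing for nodule(s): ",
         paste(cohort$id[is.na(cohort$pathology)], collapse = ", "),
         call. = FALSE)
  }
  code <- function(name) {
    if (grepl("_tirads$", name)) {
      system <- sub("_tirads$", "", name)
      return(category_rank(tirads_classify(cohort, system)))
    }
    switch(name,
      taller_than_wide   = as.numeric(cohort$taller_than_wide),
      marked_hypoechoic  = as.numeric(cohort$echogenicity == "marked_hypoechoic"),
      microcalcification = as.numeric(has_focus(cohort, "microcalcification")),
      irregular_margins  = as.numeric(cohort$margins %in%
                             c("irregular", "extrathyroidal_extension")),
      blurred_margins    = as.numeric(cohort$margins == "blurred_ill_defined"),
      doppler4d          = as.numeric(doppler4d_positive(cohort)),
      suspicious_lymph_nodes = as.numeric(cohort$suspicious_lymph_nodes),
      strain_ratio       = {
        if (anyNA(cohort$strain_ratio))
          stop("strain_ratio missing for some nodules; the design matrix ",
               "admits no missing cells", call. = FALSE)
        cohort$strain_ratio
      },
      stop("unknown predictor: ", name, call. = FALSE))
  }
  x <- vapply(predictors, code, numeric(nrow(cohort)))
  x <- matrix(x, nrow = nrow(cohort),
              dimnames = list(NULL, predictors))
  structure(list(x = x, y = as.numeric(cohort$pathology == "malignant"),
                 n = nrow(cohort)),
            class = "tirads_design")
}

#' Pearson correlation matrix of coded variables
#'
#' Pairwise Pearson correlations of the coded predictor columns and the
#' response (for a pair of 0/1 columns this is the phi coefficient; for a
#' 0/1 column against a continuous one, the point-biserial correlation).
#'
#' @param dm `tirads_design` object (the response is appended as
#'   `pathology`), or a plain numeric matrix/data.frame.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(dm) {
  m <- if (inherits(dm, "tirads_design")) {
    cbind(dm$x, pathology = dm$y)
  } else {
    as.matrix(dm)
  }
  vars <- apply(m, 2, stats::var)
  if (any(vars == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(m)[vars == 0], collapse = ", "), call. = FALSE)
  }
  stats::cor(m, method = "pearson")
}

#' Binomial logistic regression via Fisher scoring
#'
#' Maximises the binomial log-likelihood by iteratively reweighted least
#' squares (for the canonical logit link, Fisher scoring and
#' Newton-Raphson coincide).  Iterations stop when the relative deviance
#' change drops below `tol`.  Reported alongside the coefficients:
#' standard errors from the inverse Fisher information, Wald z statistics
#' with two-sided normal p-values, the residual deviance (-2 times the
#' log-likelihood; the saturated model has log-likelihood 0 for binary
#' data), `aic = deviance + 2 * (number of coefficients)`, and the
#' Fisher-scoring iteration count.
#'
#' Complete or quasi-complete separation makes the likelihood maximum
#' escape to infinity; it is detected via coefficient-norm divergence or
#' fitted probabilities pinned to 0/1, and flagged with a warning and
#' `converged = FALSE` rather than returned as silent garbage.
#'
#' @param x Numeric predictor matrix (no intercept column), or a
#'   `tirads_design` object (in which case `y` is taken from it).
#' @param y 0/1 response vector.
#' @param tol Relative deviance-change convergence tolerance.
#' @param max_iter Maximum Fisher-scoring iterations.
#' @return Object of class `tirads_glm`: `coefficients`, `se`, `wald_z`,
#'   `p_values`, `deviance`, `aic`, `n_iter`, `converged`, `n`,
#'   `deviance_trace`.
#' @export
fit_logistic <- function(x, y = NULL, tol = 1e-8, max_iter = 25L) {
  if (inherits(x, "tirads_design")) {
    y <- x$y
    x <- x$x
  }
  if (is.null(x) || length(x) == 0) {
    X <- matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
  } else {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    X <- cbind("(Intercept)" = 1, x)
  }
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  n <- length(y)
  k <- ncol(X)
  if (n <= k) stop("more coefficients than observations", call. = FALSE)
  if (all(y == y[1])) stop("response is constant", call. = FALSE)

  dev_of <- function(mu) {
    eps <- .Machine$double.xmin
    -2 * sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  }
  # start from the observation-level initialisation mu0 = (y + 1/2)/2 so
  # the first scoring step is taken from a consistent (eta, mu) state
  beta <- rep(0, k)
  mu <- (y + 0.5) / 2
  eta <- stats::qlogis(mu)
  dev <- dev_of(mu)
  trace <- numeric(0)   # deviance at each Fisher-scoring iterate
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    info <- crossprod(X, w * X)
    beta_new <- tryCatch(
      solve(info, crossprod(X, w * z)),
      error = function(e) stop("singular information matrix", call. = FALSE))
    beta <- drop(beta_new)
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    dev_new <- dev_of(mu)
    trace <- c(trace, dev_new)
    if (sqrt(sum(beta^2)) > 30 || any(mu < 1e-12) || any(mu > 1 - 1e-12)) {
      separated <- TRUE
    }
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- !separated
      break
    }
    dev <- dev_new
  }
  if (separated || !converged) {
    converged <- FALSE
    warning("possible (quasi-)separation or non-convergence; ",
            "estimates unreliable", call. = FALSE)
  }
  # Fisher information evaluated at the final coefficients
  info <- crossprod(X, (mu * (1 - mu)) * X)
  se <- sqrt(diag(solve(info)))
  wald_z <- beta / se
  p <- 2 * stats::pnorm(-abs(wald_z))
  names(beta) <- names(se) <- names(wald_z) <- names(p) <- colnames(X)
  structure(list(coefficients = beta, se = se, wald_z = wald_z,
                 p_values = p, deviance = dev, aic = dev + 2 * k,
                 n_iter = iter, converged = converged, n = n,
                 df_residual = n - k, deviance_trace = trace),
            class = "tirads_glm")
}

#' @export
print.tirads_glm <- function(x, ...) {
  cat("Binomial logistic GLM (Fisher scoring)\n")
  tab <- data.frame(estimate = x$coefficients, std_error = x$se,
                    wald_z = x$wald_z, p_value = x$p_values)
  print(format(tab, digits = 4))
  cat(sprintf("\nDeviance: %.4f   AIC: %.4f   Fisher scoring iterations: %d%s\n",
              x$deviance, x$aic, x$n_iter,
              if (x$converged) "" else "   [NOT CONVERGED]"))
  invisible(x)
}

#' Compare two fitted logistic models
#'
#' Reports both models' deviances, AICs and Fisher-scoring iteration
#' counts; the lower-AIC model is declared preferred (deviance is
#' reported as a separate, independent verdict, since it does not
#' penalise complexity).
#'
#' @param fit_a,fit_b `tirads_glm` fits on the same response.
#' @param labels Length-2 labels for the two models.
#' @return Object of class `tirads_glm_comparison`: per-model `deviance`,
#'   `aic`, `n_iter`, plus `preferred_aic` and `preferred_deviance`
#'   (a label, or `"tie"`).
#' @export
compare_models <- function(fit_a, fit_b, labels = c("model_a", "model_b")) {
  stopifnot(inherits(fit_a, "tirads_glm"), inherits(fit_b, "tirads_glm"))
  if (fit_a$n != fit_b$n) {
    stop("mismatched sample sizes: ", fit_a$n, " vs ", fit_b$n,
         call. = FALSE)
  }
  verdict <- function(a, b) {
    if (isTRUE(all.equal(a, b))) "tie" else labels[[which.min(c(a, b))]]
  }
  structure(list(
    labels = labels,
    deviance = stats::setNames(c(fit_a$deviance, fit_b$deviance), labels),
    aic = stats::setNames(c(fit_a$aic, fit_b$aic), labels),
    n_iter = stats::setNames(c(fit_a$n_iter, fit_b$n_iter), labels),
    preferred_aic = verdict(fit_a$aic, fit_b$aic),
    preferred_deviance = verdict(fit_a$deviance, fit_b$deviance)
  ), class = "tirads_glm_comparison")
}

#' @export
print.tirads_glm_comparison <- function(x, ...) {
  tab <- data.frame(deviance = x$deviance, aic = x$aic,
                    fisher_iterations = x$n_iter)
  print(format(tab, digits = 6))
  cat(sprintf("\nPreferred by AIC: %s (lower AIC is better)\n",
              x$preferred_aic))
  cat(sprintf("Lower deviance: %s\n", x$preferred_deviance))
  invisible(x)
}
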