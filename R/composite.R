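# Three-component composite-material models and their inversion, plus the
# isotropic elasticity relation G = 3KE/(9K - E).
#
# Mixture rule / parallel model:  X_c = f_p X_p + f_w1 X_w1 + f_w2 X_w2
# Series model:                 1/X_c = f_p/X_p + f_w1/X_w1 + f_w2/X_w2
# (identical mathematics for mixture and parallel; they differ in physical
# interpretation: scalar composites vs tensorial parallel loading).

MODEL_KINDS <- c("mixture", "parallel", "series")
PARAM_NAMES <- c("X_p", "X_w1", "X_w2")

#' Property curve over a moisture grid
#'
#' A material property sampled on a moisture-content grid, optionally with
#' per-point volume fractions (needed for composite fitting) and per-point
#' uncertainties.
#'
#' @param m Moisture contents.
#' @param value Property values, same length.
#' @param fractions Optional [generate_fraction_schedule()]-style data frame
#'   (columns m, f_p, f_w1, f_w2) aligned to `m`.
#' @param property,units Optional labels (e.g. "K", "GPa").
#' @param sd Optional per-point standard deviations (inverse-variance
#'   weights in fitting).
#' @return Object of class `property_curve` (a data frame).
#' @export
property_curve <- function(m, value, fractions = NULL, property = NULL,
                           units = NULL, sd = NULL) {
  m <- as.numeric(m); value <- as.numeric(value)
  if (length(m) != length(value)) stop("m and value lengths differ")
  out <- data.frame(m = m, value = value)
  if (!is.null(sd)) {
    if (length(sd) != length(m) || any(sd <= 0)) {
      stop("sd must be positive and aligned to m")
    }
    out$sd <- as.numeric(sd)
  }
  if (!is.null(fractions)) {
    if (!all(c("m", "f_p", "f_w1", "f_w2") %in% names(fractions))) {
      stop("fractions must have columns m, f_p, f_w1, f_w2")
    }
    if (nrow(fractions) != length(m) ||
        max(abs(fractions$m - m)) > 1e-9 * max(1, max(abs(m)))) {
      stop("fraction schedule grid does not match the curve's m grid")
    }
    out$f_p <- fractions$f_p
    out$f_w1 <- fractions$f_w1
    out$f_w2 <- fractions$f_w2
  }
  attr(out, "property") <- property
  attr(out, "units") <- units
  class(out) <- c("property_curve", "data.frame")
  out
}

check_fractions <- function(f_p, f_w1, f_w2, tol = 1e-6) {
  if (any(f_p < -tol) || any(f_w1 < -tol) || any(f_w2 < -tol)) {
    stop("volume fractions must be non-negative")
  }
  s <- f_p + f_w1 + f_w2
  if (any(abs(s - 1) > tol)) {
    stop("volume fractions must sum to 1 (max deviation ",
         signif(max(abs(s - 1)), 3), ")")
  }
}

#' Forward evaluation of the composite models
#'
#' @param model_kind `"mixture"`, `"parallel"` or `"series"`.
#' @param X_p,X_w1,X_w2 Component properties (series: strictly positive).
#' @param f_p,f_w1,f_w2 Volume fractions (vectors allowed), non-negative,
#'   summing to 1 within 1e-6.
#' @return Composite property value(s).
#' @export
composite_predict <- function(model_kind, X_p, X_w1, X_w2,
                              f_p, f_w1, f_w2) {
  model_kind <- match.arg(tolower(model_kind), MODEL_KINDS)
  check_fractions(f_p, f_w1, f_w2)
  if (model_kind == "series") {
    if (any(c(X_p, X_w1, X_w2) <= 0)) {
      stop("series model requires strictly positive component properties")
    }
    1 / (f_p / X_p + f_w1 / X_w1 + f_w2 / X_w2)
  } else {
    f_p * X_p + f_w1 * X_w1 + f_w2 * X_w2
  }
}

#' Shear modulus of an isotropic material from bulk and Young's moduli
#'
#' `G = 3KE / (9K - E)`; valid while `9K > E`.
#'
#' @param K Bulk modulus, GPa.
#' @param E Young's modulus, GPa.
#' @return Shear modulus, GPa.
#' @export
shear_from_isotropy <- function(K, E) {
  if (any(9 * K - E <= 0)) {
    stop("9K - E must be positive for an isotropic material")
  }
  3 * K * E / (9 * K - E)
}

#' Default composite model for a property
#'
#' Mechanical moduli (K, E, G) follow the series model, heat of adsorption
#' (Q) and heat capacity (CP) the mixture rule, and the thermal expansion
#' coefficient (ALPHA) the parallel model.
#'
#' @param property One of "K", "E", "G", "Q", "CP", "ALPHA".
#' @return A model kind string.
#' @export
default_model_kind <- function(property) {
  switch(toupper(property),
         K = , E = , G = "series",
         Q = , CP = "mixture",
         ALPHA = "parallel",
         stop("no default model kind for property '", property, "'"))
}

fraction_design <- function(curve) {
  if (!all(c("f_p", "f_w1", "f_w2") %in% names(curve))) {
    stop("curve has no attached volume fractions; composite fitting needs ",
         "them")
  }
  F <- as.matrix(curve[, c("f_p", "f_w1", "f_w2")])
  colnames(F) <- PARAM_NAMES
  F
}

check_identifiable <- function(F) {
  qrF <- qr(F)
  if (qrF$rank < 3) {
    sds <- apply(F, 2, sd)
    culprit <- PARAM_NAMES[which.min(sds)]
    stop("fraction design is rank-deficient: parameter ", culprit,
         " is not identifiable (its fraction column does not vary ",
         "independently across the moisture grid)")
  }
}

#' Fit a three-component composite model to a property curve
#'
#' Least-squares estimation of the component properties (X_p, X_w1, X_w2)
#' from composite values and per-point volume fractions. Mixture/parallel is
#' a linear solve. The series model is first solved in closed form on the
#' reciprocal response (1/X_c is linear in the reciprocal parameters), then
#' polished by bounded nonlinear least squares on the original scale.
#' Standard errors come from the local quadratic approximation at the
#' optimum. If the curve carries an `sd` column, points are weighted by
#' inverse variance.
#'
#' @param model_kind `"mixture"`, `"parallel"` or `"series"`.
#' @param curve A [property_curve()] with fractions attached and >= 4 points.
#' @return Object of class `composite_fit`: fields model_kind, X_p, X_w1,
#'   X_w2, se (named vector), rss, fitted, df_residual.
#' @export
fit_composite <- function(model_kind, curve) {
  model_kind <- match.arg(tolower(model_kind), MODEL_KINDS)
  stopifnot(inherits(curve, "property_curve"))
  if (nrow(curve) < 4) stop("composite fitting needs at least 4 grid points")
  F <- fraction_design(curve)
  check_fractions(F[, 1], F[, 2], F[, 3])
  check_identifiable(F)
  y <- curve$value
  w <- if ("sd" %in% names(curve)) 1 / curve$sd^2 else rep(1, length(y))

  if (model_kind != "series") {
    fit <- lm(y ~ 0 + F, weights = w)
    beta <- unname(coef(fit))
    fitted <- drop(F %*% beta)
    res <- y - fitted
    dfres <- length(y) - 3L
    sigma2 <- sum(w * res^2) / dfres
    cov <- sigma2 * solve(crossprod(F * sqrt(w)))
    se <- sqrt(diag(cov))
  } else {
    if (any(y <= 0)) {
      stop("series model requires strictly positive composite values")
    }
    # closed-form start on the reciprocal scale: 1/y = F %*% theta
    theta0 <- qr.solve(F * sqrt(w), sqrt(w) / y)
    theta0 <- pmax(theta0, 1e-12)
    obj <- function(theta) {
      pred <- 1 / drop(F %*% theta)
      sum(w * (y - pred)^2)
    }
    opt <- stats::optim(theta0, obj, method = "L-BFGS-B",
                        lower = rep(1e-12, 3),
                        control = list(factr = 1e4, maxit = 500))
    theta <- unname(opt$par)
    beta <- 1 / theta
    s <- drop(F %*% theta)
    fitted <- 1 / s
    res <- y - fitted
    dfres <- length(y) - 3L
    sigma2 <- sum(w * res^2) / dfres
    # Jacobian of predictions wrt beta_k: (f_k / beta_k^2) / s^2
    J <- sweep(F, 2, beta^2, "/") / s^2
    JtJ <- crossprod(J * sqrt(w))
    cov <- tryCatch(sigma2 * solve(JtJ), error = function(e)
      matrix(NA_real_, 3, 3))
    se <- sqrt(pmax(diag(cov), 0))
  }
  structure(list(model_kind = model_kind,
                 X_p = beta[1], X_w1 = beta[2], X_w2 = beta[3],
                 se = setNames(se, PARAM_NAMES),
                 rss = sum((y - fitted)^2), fitted = fitted,
                 df_residual = length(y) - 3L),
            class = "composite_fit")
}

#' @export
print.composite_fit <- function(x, ...) {
  cat(sprintf("composite fit (%s model):\n", x$model_kind))
  for (p in PARAM_NAMES) {
    cat(sprintf("  %-5s = %.6g  (se %.3g)\n", p, x[[p]], x$se[[p]]))
  }
  cat(sprintf("  rss = %.4g on %d residual df\n", x$rss, x$df_residual))
  invisible(x)
}
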