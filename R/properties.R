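# Property estimators from tabulated observable series: heat of adsorption,
# thermal expansion coefficient, heat capacity, elastic moduli and Poisson's
# ratio. All slope estimates are ordinary least squares over the supplied
# window; windowing is the caller's responsibility.

SERIES_KINDS <- c("generic", "length_vs_temperature",
                  "enthalpy_vs_temperature", "stress_vs_strain",
                  "strain_vs_strain")

#' Tabulated observable series
#'
#' A strictly monotone abscissa (temperature, strain, pressure, ...) with a
#' matching ordinate (box length, enthalpy, stress, ...).
#'
#' @param x,y Equal-length numeric vectors (>= 3 points); x strictly
#'   monotone.
#' @param kind One of `r paste0('"', SERIES_KINDS, '"', collapse = ", ")`.
#' @return Object of class `observable_series`.
#' @export
observable_series <- function(x, y, kind = "generic") {
  kind <- match.arg(kind, SERIES_KINDS)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  dx <- diff(x)
  if (!(all(dx > 0) || all(dx < 0))) stop("x must be strictly monotone")
  structure(list(x = x, y = y, kind = kind), class = "observable_series")
}

ols_slope <- function(x, y) {
  fit <- lm(y ~ x)
  unname(coef(fit)[2])
}

#' Integral heat of adsorption from potential energies
#'
#' Energy released per unit mass of adsorbed water, referenced to isolated
#' water vapor:
#' `Q = (U_dry + n_water * u_ref_vapor - U_hydrated) / (n_water * 0.018015)`.
#' With that reference, large moisture contents tend toward the latent-heat
#' scale of bulk liquid water. `u_ref_vapor` must be supplied explicitly.
#'
#' @param U_dry Potential energy of the dry system, kJ/mol.
#' @param U_hydrated Potential energy of the hydrated system, kJ/mol.
#' @param n_water Number of adsorbed water molecules (>= 1).
#' @param u_ref_vapor Reference energy of one isolated vapor water molecule,
#'   kJ/mol.
#' @return Heat of adsorption in kJ per kg of water.
#' @export
heat_of_adsorption <- function(U_dry, U_hydrated, n_water, u_ref_vapor) {
  if (n_water < 1) stop("n_water must be >= 1")
  (U_dry + n_water * u_ref_vapor - U_hydrated) /
    (n_water * WATER_MOLAR_MASS * 1e-3)
}

#' Uniaxial thermal expansion coefficient from a length-temperature series
#'
#' `alpha_X = (1/L(T0)) * dL/dT`, with the slope and `L(T0)` from one
#' ordinary least-squares line through the series.
#'
#' @param series An [observable_series()] of box length (nm) vs temperature
#'   (K), kind `"length_vs_temperature"`.
#' @param T0 Reference temperature, K (default 300); must lie inside the
#'   fitted range.
#' @return Expansion coefficient in 1/K.
#' @export
thermal_expansion_coefficient <- function(series, T0 = 300) {
  stopifnot(inherits(series, "observable_series"))
  if (series$kind != "length_vs_temperature") {
    stop("series must be of kind 'length_vs_temperature'")
  }
  if (T0 < min(series$x) || T0 > max(series$x)) {
    stop("T0 = ", T0, " K lies outside the fitted temperature range")
  }
  fit <- lm(y ~ x, data = list(x = series$x, y = series$y))
  L0 <- unname(coef(fit)[1] + coef(fit)[2] * T0)
  unname(coef(fit)[2]) / L0
}

#' Specific heat capacity from an enthalpy-temperature series
#'
#' `C_p = (dH/dT) / mass` by ordinary least squares.
#'
#' @param series An [observable_series()] of enthalpy (kJ) vs temperature
#'   (K), kind `"enthalpy_vs_temperature"`.
#' @param mass System mass, kg (> 0).
#' @return Heat capacity in kJ/(kg K).
#' @export
heat_capacity <- function(series, mass) {
  stopifnot(inherits(series, "observable_series"))
  if (series$kind != "enthalpy_vs_temperature") {
    stop("series must be of kind 'enthalpy_vs_temperature'")
  }
  if (mass <= 0) stop("mass must be > 0")
  ols_slope(series$x, series$y) / mass
}

#' Elastic modulus from a stress-strain series
#'
#' Least-squares slope of stress against strain restricted to
#' `|strain| <= max_strain`. The same estimator serves uniaxial (Young's),
#' volumetric (bulk, strain = dV/V, stress = -dP) and shear loadings.
#'
#' @param series An [observable_series()] of stress (GPa) vs strain
#'   (dimensionless), kind `"stress_vs_strain"`.
#' @param max_strain Linear-window half-width (default Inf: use all points).
#' @return Modulus in the stress units of the series (GPa for GPa input).
#' @export
modulus_from_stress_strain <- function(series, max_strain = Inf) {
  stopifnot(inherits(series, "observable_series"))
  if (series$kind != "stress_vs_strain") {
    stop("series must be of kind 'stress_vs_strain'")
  }
  keep <- abs(series$x) <= max_strain
  if (sum(keep) < 3) stop("fewer than 3 points inside |strain| <= max_strain")
  ols_slope(series$x[keep], series$y[keep])
}

#' Poisson's ratio from paired strain series
#'
#' `nu = -(slope of transverse vs axial strain)` by ordinary least squares.
#'
#' @param axial,transverse Aligned [observable_series()] (or numeric
#'   vectors) of axial and transverse strain.
#' @return Dimensionless Poisson's ratio.
#' @export
poissons_ratio <- function(axial, transverse) {
  as_strain <- function(s, what) {
    if (inherits(s, "observable_series")) s$y else as.numeric(s)
  }
  if (inherits(axial, "observable_series") &&
      inherits(transverse, "observable_series") &&
      (length(axial$x) != length(transverse$x) ||
       any(axial$x != transverse$x))) {
    stop("axial and transverse series must share the same loading grid")
  }
  ax <- as_strain(axial)
  tv <- as_strain(transverse)
  if (length(ax) != length(tv)) stop("axial and transverse lengths differ")
  -ols_slope(ax, tv)
}
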