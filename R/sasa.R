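# Rolling-ball (Shrake-Rupley) surface areas and the polymer-water contact
# area A_contact = A_polymer + A_water - A_system.
#
# The surface is the one traced by the CENTER of the probe ball (radius
# r_vdw + probe), the standard SASA convention. Probe radius defaults to
# 0.1 nm (1 Angstrom), not the conventional 0.14 nm water probe. Periodic
# images participate in burial tests.

#' Quasi-uniform points on the unit sphere (golden spiral)
#'
#' @param n Number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  .fibonacci_sphere_cpp(as.integer(n))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, `n_sphere_points` golden-spiral points are distributed on
#' the sphere of radius `r_vdw + probe_radius`; a point is exposed if it lies
#' outside every other atom's expanded sphere (minimum image on periodic
#' axes). The area is `4*pi*(r_vdw+probe)^2 * exposed_fraction`, summed over
#' atoms.
#'
#' @param coords n x 3 matrix of positions (nm) or a [configuration()] (all
#'   atoms used).
#' @param radii Per-atom van der Waals radii, nm (taken from the
#'   configuration if `coords` is one).
#' @param box A [new_box()]; required when `coords` is a matrix.
#' @param probe_radius Probe radius, nm (default 0.1).
#' @param n_sphere_points Points per atom (default 960, >= 12).
#' @param per_atom Return the per-atom area vector instead of the total.
#' @return Total area in nm^2 (or per-atom vector).
#' @export
shrake_rupley_area <- function(coords, radii = NULL, box = NULL,
                               probe_radius = 0.1, n_sphere_points = 960,
                               per_atom = FALSE) {
  if (inherits(coords, "pw_config")) {
    radii <- coords$atoms$vdw_radius
    box <- coords$box
    coords <- coords_of(coords)
  }
  stopifnot(probe_radius >= 0, n_sphere_points >= 12, inherits(box, "box"))
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) == 0) {
    warning("zero atoms: surface area is 0")
    return(if (per_atom) numeric(0) else 0)
  }
  if (length(radii) != nrow(coords)) stop("radii must match coords rows")
  a <- .sasa_cpp(coords, as.numeric(radii), probe_radius,
                 as.integer(n_sphere_points), box$lengths, box$periodic)
  if (per_atom) a else sum(a)
}

#' Polymer-water contact area
#'
#' Computes the rolling-ball areas of the polymer atoms alone, the water
#' atoms alone, and the full system, and the contact area by the identity
#' `A_contact = A_polymer + A_water - A_system`.
#'
#' @param config A [configuration()].
#' @param probe_radius Probe radius, nm (default 0.1).
#' @param n_sphere_points Points per atom (default 960).
#' @return Object of class `surface_areas` with fields A_polymer, A_water,
#'   A_system, A_contact (nm^2), probe_radius, n_sphere_points.
#' @export
contact_area <- function(config, probe_radius = 0.1, n_sphere_points = 960) {
  a <- config$atoms
  poly <- a$role == "polymer"
  wat <- !poly
  area_of <- function(rows) {
    if (!any(rows)) return(0)
    shrake_rupley_area(coords_of(config, which(rows)), a$vdw_radius[rows],
                       config$box, probe_radius, n_sphere_points)
  }
  A_polymer <- area_of(poly)
  A_water <- suppressWarnings(area_of(wat))
  A_system <- shrake_rupley_area(coords_of(config), a$vdw_radius, config$box,
                                 probe_radius, n_sphere_points)
  structure(list(A_polymer = A_polymer, A_water = A_water,
                 A_system = A_system,
                 A_contact = A_polymer + A_water - A_system,
                 probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points),
            class = "surface_areas")
}

#' @export
print.surface_areas <- function(x, ...) {
  cat(sprintf(paste0("rolling-ball areas (probe %.2f nm, %d pts/atom): ",
                     "polymer %.2f, water %.2f, system %.2f, ",
                     "contact %.2f nm^2\n"),
              x$probe_radius, x$n_sphere_points, x$A_polymer, x$A_water,
              x$A_system, x$A_contact))
  invisible(x)
}
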