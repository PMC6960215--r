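# Periodic-box geometry and the configuration data model.
#
# Internal length unit is nm everywhere; layer/histogram reporting converts to
# Angstrom only at the presentation boundary. Only orthorhombic boxes are
# supported.

AVOGADRO <- 6.02214076e23
WATER_MOLAR_MASS <- 18.015            # g/mol
GPMOL_PER_NM3_TO_GCM3 <- 1e21 / AVOGADRO  # (g/mol)/nm^3 -> g/cm^3

# Standard atomic masses (g/mol), IUPAC 2021 abridged.
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Cl = 35.45, Na = 22.99, K = 39.098, Mg = 24.305, Ca = 40.078
)

# Bondi van der Waals radii (nm).
BONDI_RADII <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180, P = 0.180,
  F = 0.147, Cl = 0.175, Na = 0.227, K = 0.275, Mg = 0.173, Ca = 0.231
)

ATOM_ROLES <- c("polymer", "water_O", "water_H")

#' Standard atomic mass of an element
#'
#' @param element Character vector of chemical symbols.
#' @return Atomic masses in g/mol.
#' @export
atomic_mass <- function(element) {
  m <- ATOMIC_MASSES[element]
  if (anyNA(m)) {
    stop("no atomic mass tabulated for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Bondi van der Waals radius of an element
#'
#' @param element Character vector of chemical symbols.
#' @return Radii in nm.
#' @export
bondi_radius <- function(element) {
  r <- BONDI_RADII[element]
  if (anyNA(r)) {
    stop("no Bondi radius tabulated for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Orthorhombic periodic box
#'
#' @param lengths Numeric length-3 vector of box edge lengths in nm.
#' @param periodic Logical scalar or length-3 vector: periodicity per axis.
#' @return An object of class `box`.
#' @export
new_box <- function(lengths, periodic = TRUE) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 1) lengths <- rep(lengths, 3)
  if (length(lengths) != 3 || !all(is.finite(lengths)) || any(lengths <= 0)) {
    stop("box lengths must be 3 positive finite numbers (nm)")
  }
  periodic <- as.logical(periodic)
  if (length(periodic) == 1) periodic <- rep(periodic, 3)
  if (length(periodic) != 3 || anyNA(periodic)) {
    stop("periodic must be a logical scalar or length-3 vector")
  }
  structure(list(lengths = lengths, periodic = periodic), class = "box")
}

#' @export
print.box <- function(x, ...) {
  cat(sprintf("orthorhombic box: %.4f x %.4f x %.4f nm (periodic: %s)\n",
              x$lengths[1], x$lengths[2], x$lengths[3],
              paste(ifelse(x$periodic, "T", "F"), collapse = "")))
  invisible(x)
}

box_volume <- function(box) prod(box$lengths)

#' Minimum-image distance between two points
#'
#' Shortest distance between two points over all periodic images of an
#' orthorhombic box.
#'
#' @param p1,p2 Numeric length-3 position vectors (nm).
#' @param box A [new_box()] object.
#' @return Distance in nm.
#' @export
minimum_image_distance <- function(p1, p2, box) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 3 || length(p2) != 3 ||
      !all(is.finite(p1)) || !all(is.finite(p2))) {
    stop("corrupt input: positions must be finite length-3 vectors")
  }
  d <- p2 - p1
  L <- box$lengths
  w <- which(box$periodic)
  d[w] <- d[w] - L[w] * round(d[w] / L[w])
  sqrt(sum(d * d))
}

# Vectorised minimum-image displacement of point sets: rows of `a` minus a
# single point `p` (or matching rows). Returns a matrix of displacements.
min_image_disp <- function(a, p, box) {
  d <- sweep(a, 2, p)
  L <- box$lengths
  for (k in which(box$periodic)) {
    d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
  }
  d
}

# Minimum-image distances from every row of `a` (n x 3) to every row of
# `b` (m x 3): returns an n x m matrix. Memory ~ 3*n*m doubles; callers chunk.
min_image_cross_dist <- function(a, b, box) {
  L <- box$lengths
  total <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    if (box$periodic[k]) d <- d - L[k] * round(d / L[k])
    total <- total + d * d
  }
  sqrt(total)
}

# Wrap coordinates into [0, L) on periodic axes.
wrap_coords <- function(xyz, box) {
  L <- box$lengths
  for (k in which(box$periodic)) {
    xyz[, k] <- xyz[, k] - L[k] * floor(xyz[, k] / L[k])
  }
  xyz
}

#' Build an atom table
#'
#' Helper that assembles the per-atom data frame used by [configuration()].
#' Masses and van der Waals radii default from the element symbol.
#'
#' @param xyz n x 3 matrix of positions, nm.
#' @param role Atom roles, one of `"polymer"`, `"water_O"`, `"water_H"`.
#' @param element Chemical symbols.
#' @param molecule_id Integer molecule grouping.
#' @param mass Optional explicit masses (g/mol); coarse-grained beads carry a
#'   monomer mass that no element table supplies.
#' @param vdw_radius Optional explicit van der Waals radii (nm).
#' @return A data frame with columns x, y, z, role, element, mass,
#'   vdw_radius, molecule_id.
#' @export
atom_table <- function(xyz, role, element, molecule_id,
                       mass = NULL, vdw_radius = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  role <- match.arg(as.character(role), ATOM_ROLES, several.ok = TRUE)
  role <- rep_len(role, n)
  element <- rep_len(as.character(element), n)
  molecule_id <- rep_len(as.integer(molecule_id), n)
  if (is.null(mass)) mass <- atomic_mass(element)
  if (is.null(vdw_radius)) vdw_radius <- bondi_radius(element)
  mass <- rep_len(as.numeric(mass), n)
  vdw_radius <- rep_len(as.numeric(vdw_radius), n)
  if (any(vdw_radius <= 0)) stop("vdw_radius must be > 0")
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             role = role, element = element, mass = mass,
             vdw_radius = vdw_radius, molecule_id = molecule_id,
             stringsAsFactors = FALSE)
}

validate_waters <- function(atoms) {
  w <- atoms$role != "polymer"
  if (!any(w)) return(invisible(TRUE))
  tab <- table(atoms$molecule_id[w], atoms$role[w])
  nO <- if ("water_O" %in% colnames(tab)) tab[, "water_O"] else 0
  nH <- if ("water_H" %in% colnames(tab)) tab[, "water_H"] else 0
  if (any(nO != 1) || any(nH != 2)) {
    stop("every water molecule must have exactly one water_O and two water_H ",
         "sharing a molecule_id")
  }
  invisible(TRUE)
}

#' Atomistic configuration of a polymer + water system
#'
#' Bundles an atom table with an orthorhombic periodic box and bookkeeping
#' (moisture content, frame index). Coordinates are wrapped into the box on
#' construction; the stored moisture content must agree with the mass ratio
#' computed from the atoms.
#'
#' @param atoms Data frame from [atom_table()].
#' @param box A [new_box()] object.
#' @param moisture_content Optional dimensionless mass ratio m = m_w/m_p; if
#'   omitted it is computed from the atoms. A supplied value disagreeing with
#'   the computed ratio by more than 1e-6 (relative) is an error.
#' @param frame_index Integer frame label (default 1).
#' @param validate Check water-molecule composition (default TRUE).
#' @return An object of class `pw_config`.
#' @export
configuration <- function(atoms, box, moisture_content = NULL,
                          frame_index = 1L, validate = TRUE) {
  stopifnot(inherits(box, "box"), is.data.frame(atoms))
  need <- c("x", "y", "z", "role", "element", "mass", "vdw_radius",
            "molecule_id")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  xyz <- wrap_coords(as.matrix(atoms[, c("x", "y", "z")]), box)
  atoms[, c("x", "y", "z")] <- xyz
  if (validate) validate_waters(atoms)
  cfg <- structure(list(atoms = atoms, box = box,
                        moisture_content = 0, frame_index = as.integer(frame_index)),
                   class = "pw_config")
  m_calc <- moisture_content_of(cfg)
  if (!is.null(moisture_content)) {
    if (abs(moisture_content - m_calc) > 1e-6 * max(1, abs(m_calc))) {
      stop(sprintf(paste0("declared moisture content %.8f disagrees with the ",
                          "mass ratio computed from atoms (%.8f)"),
                   moisture_content, m_calc))
    }
  }
  cfg$moisture_content <- m_calc
  cfg
}

#' @export
print.pw_config <- function(x, ...) {
  np <- sum(x$atoms$role == "polymer")
  nw <- sum(x$atoms$role == "water_O")
  cat(sprintf(paste0("hydrated-polymer configuration: %d atoms ",
                     "(%d polymer, %d waters), m = %.4f\n"),
              nrow(x$atoms), np, nw, x$moisture_content))
  print(x$box)
  invisible(x)
}

coords_of <- function(config, rows = TRUE) {
  as.matrix(config$atoms[rows, c("x", "y", "z")])
}

#' Moisture content of a configuration
#'
#' Mass of water divided by the mass of dry polymer, m = m_w/m_p, computed
#' from the per-atom masses.
#'
#' @param config A [configuration()].
#' @return Dimensionless mass ratio.
#' @export
moisture_content_of <- function(config) {
  a <- config$atoms
  mp <- sum(a$mass[a$role == "polymer"])
  if (mp <= 0) stop("configuration has no polymer mass")
  mw <- sum(a$mass[a$role != "polymer"])
  mw / mp
}

#' Mass density of a configuration
#'
#' Total mass over box volume, in g/cm^3.
#'
#' @param config A [configuration()].
#' @return Density in g/cm^3.
#' @export
mass_density <- function(config) {
  sum(config$atoms$mass) / box_volume(config$box) * GPMOL_PER_NM3_TO_GCM3
}
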