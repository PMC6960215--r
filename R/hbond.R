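# Geometric hydrogen-bond detection and class-resolved densities.
#
# A bond is a (donor O, donor H, acceptor O) triple with donor-acceptor
# oxygen distance r < r_max and angle alpha < alpha_max, where alpha is taken
# AT THE DONOR OXYGEN between the O->acceptor and O->H vectors (not the
# H-centered angle many tools use). All qualifying triples are counted; no
# exclusivity rule is applied.

#' Geometric hydrogen-bond criteria
#'
#' @param r_max Donor O - acceptor O distance cutoff, nm (default 0.35).
#' @param alpha_max Acceptor O - donor O - donor H angle cutoff, degrees
#'   (default 30).
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(r_max = 0.35, alpha_max = 30) {
  if (r_max <= 0) stop("r_max must be > 0")
  if (alpha_max <= 0 || alpha_max >= 180) stop("alpha_max must be in (0, 180)")
  structure(list(r_max = r_max, alpha_max = alpha_max),
            class = "hbond_criteria")
}

#' Infer the covalent O-H donor map from geometry
#'
#' Pairs every hydrogen with the oxygen it is covalently bonded to, inferred
#' by an O-H distance below `oh_cutoff` (minimum image). Hydrogens with no
#' oxygen within the cutoff are not donatable and are dropped.
#'
#' @param config A [configuration()].
#' @param oh_cutoff Covalent O-H distance cutoff, nm (default 0.12).
#' @return Data frame with columns `H` and `O` (atom row indices).
#' @export
infer_donor_map <- function(config, oh_cutoff = 0.12) {
  a <- config$atoms
  iH <- which(a$element == "H")
  iO <- which(a$element == "O")
  if (!length(iH) || !length(iO)) {
    return(data.frame(H = integer(), O = integer()))
  }
  d <- min_image_cross_dist(coords_of(config, iH), coords_of(config, iO),
                            config$box)
  nearest <- max.col(-d)
  keep <- d[cbind(seq_along(iH), nearest)] < oh_cutoff
  data.frame(H = iH[keep], O = iO[nearest[keep]])
}

pair_class_of <- function(role_a, role_b) {
  pa <- role_a == "polymer"
  pb <- role_b == "polymer"
  ifelse(pa & pb, "polymer_polymer",
         ifelse(!pa & !pb, "water_water", "polymer_water"))
}

#' Detect hydrogen bonds by geometric criteria
#'
#' Returns every (donor O-H, acceptor O) triple with donor-acceptor distance
#' `r < r_max` and donor-oxygen-centered angle `alpha < alpha_max`, under
#' minimum-image distances. Both polymer and water oxygens may donate and
#' accept; the pair class is `polymer_water` regardless of which side
#' donates.
#'
#' @param config A [configuration()].
#' @param criteria An [hbond_criteria()].
#' @param donor_map Covalent O-H pairing as from [infer_donor_map()]; by
#'   default inferred from geometry. Every H in the map must reference an
#'   oxygen atom.
#' @return Data frame of class `hbond_records`: columns donor_O, donor_H,
#'   acceptor_O (atom row indices), pair_class, r (nm), alpha (degrees).
#' @export
detect_hbonds <- function(config, criteria = hbond_criteria(),
                          donor_map = NULL) {
  a <- config$atoms
  if (is.null(donor_map)) donor_map <- infer_donor_map(config)
  if (nrow(donor_map) &&
      !all(a$element[donor_map$O] == "O" & a$element[donor_map$H] == "H")) {
    stop("donor_map must pair hydrogen atoms with oxygen atoms")
  }
  empty <- data.frame(donor_O = integer(), donor_H = integer(),
                      acceptor_O = integer(), pair_class = character(),
                      r = numeric(), alpha = numeric())
  class(empty) <- c("hbond_records", "data.frame")
  iO <- which(a$element == "O")
  if (!nrow(donor_map) || length(iO) < 2) return(empty)
  box <- config$box
  posO <- coords_of(config, iO)
  # candidate donor-acceptor oxygen pairs within r_max
  dOO <- min_image_cross_dist(posO, posO, box)
  donors <- unique(donor_map$O)
  rows <- list()
  for (dO in donors) {
    di <- match(dO, iO)
    acc <- iO[which(dOO[di, ] < criteria$r_max & iO != dO)]
    if (!length(acc)) next
    hs <- donor_map$H[donor_map$O == dO]
    pO <- as.numeric(a[dO, c("x", "y", "z")])
    vacc <- min_image_disp(coords_of(config, acc), pO, box)    # O -> acceptor
    vh <- min_image_disp(coords_of(config, hs), pO, box)       # O -> H
    r <- sqrt(rowSums(vacc^2))
    for (j in seq_along(hs)) {
      h <- vh[j, ]
      cosa <- (vacc %*% h) / (r * sqrt(sum(h^2)))
      alpha <- acos(pmin(1, pmax(-1, cosa))) * 180 / pi
      ok <- alpha < criteria$alpha_max
      if (any(ok)) {
        rows[[length(rows) + 1L]] <- data.frame(
          donor_O = dO, donor_H = hs[j], acceptor_O = acc[ok],
          pair_class = pair_class_of(a$role[dO], a$role[acc[ok]]),
          r = r[ok], alpha = alpha[ok])
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hbond_records", "data.frame")
  out
}

#' Hydrogen-bond density normalized by dry volume
#'
#' Count of bonds of a class divided by the initial dry material volume V0.
#' With a list of per-frame bond tables the time-averaged count is used.
#'
#' @param bonds An `hbond_records` data frame, or a list of them (one per
#'   frame).
#' @param pair_class `"polymer_polymer"`, `"polymer_water"` or
#'   `"water_water"`.
#' @param V0 Dry material volume, nm^3 (> 0).
#' @return Density in bonds per nm^3.
#' @export
hbond_density <- function(bonds, pair_class, V0) {
  pair_class <- match.arg(pair_class,
                          c("polymer_polymer", "polymer_water", "water_water"))
  if (!is.numeric(V0) || V0 <= 0) stop("V0 must be > 0")
  if (is.data.frame(bonds)) bonds <- list(bonds)
  counts <- vapply(bonds, function(b) sum(b$pair_class == pair_class), 0)
  mean(counts) / V0
}
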