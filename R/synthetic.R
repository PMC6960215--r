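# Synthetic-data generators: bead-chain polymer configurations at a target
# density, hydration with a prescribed two-Gaussian nearest-distance shell
# structure, layer volume-fraction schedules, composite property curves and
# linear observable series. All generators are deterministic given a seed.

#' Two-Gaussian hydration-shell mixture parameters
#'
#' Describes the distribution of the nearest polymer-atom distance of water
#' oxygens as a two-component Gaussian mixture: a first adsorbed shell in
#' contact with the polymer and a second, more diffuse shell. Defaults put the
#' shells at 2.8 and 5.6 Angstrom.
#'
#' @param mean1,mean2 Shell centers, nm (`mean1 < mean2`).
#' @param sd1,sd2 Shell widths, nm (> 0).
#' @param weight1 Mixture weight of the first shell, in \[0, 1\].
#' @return An object of class `shell_mixture`.
#' @export
shell_mixture <- function(mean1 = 0.28, sd1 = 0.05,
                          mean2 = 0.56, sd2 = 0.15, weight1 = 0.6) {
  if (!(mean1 > 0 && mean1 < mean2)) stop("need 0 < mean1 < mean2")
  if (sd1 <= 0 || sd2 <= 0) stop("shell sds must be > 0")
  if (weight1 < 0 || weight1 > 1) stop("weight1 must lie in [0, 1]")
  structure(list(mean1 = mean1, sd1 = sd1, mean2 = mean2, sd2 = sd2,
                 weight1 = weight1), class = "shell_mixture")
}

# Density (unnormalised by truncation) and CDF of the shell mixture.
shell_mixture_density <- function(d, shells, d_min = 0) {
  z <- shells$weight1 * (1 - stats::pnorm(d_min, shells$mean1, shells$sd1)) +
    (1 - shells$weight1) * (1 - stats::pnorm(d_min, shells$mean2, shells$sd2))
  (shells$weight1 * stats::dnorm(d, shells$mean1, shells$sd1) +
      (1 - shells$weight1) * stats::dnorm(d, shells$mean2, shells$sd2)) *
    (d >= d_min) / z
}

shell_mixture_cdf <- function(d, shells, d_min = 0) {
  num <- function(x)
    shells$weight1 * stats::pnorm(x, shells$mean1, shells$sd1) +
    (1 - shells$weight1) * stats::pnorm(x, shells$mean2, shells$sd2)
  z <- 1 - num(d_min)
  pmax(0, (num(d) - num(d_min))) / z
}

sample_shell_mixture <- function(n, shells, d_min = 0) {
  out <- numeric(0)
  while (length(out) < n) {
    k <- max(n - length(out), 16L)
    comp <- stats::runif(k) < shells$weight1
    d <- ifelse(comp, stats::rnorm(k, shells$mean1, shells$sd1),
                stats::rnorm(k, shells$mean2, shells$sd2))
    out <- c(out, d[d >= d_min])
  }
  out[seq_len(n)]
}

random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a dry bead-chain polymer configuration
#'
#' Self-avoiding random-walk bead chains in a cubic periodic box whose edge is
#' chosen so that total mass / volume equals the target density exactly. Each
#' bead stands for one monomer; the model is purely geometric (positions,
#' radii, roles), which is all the downstream statistics use.
#'
#' @param n_chains Number of chains.
#' @param beads_per_chain Beads per chain.
#' @param target_density Dry density, g/cm^3 (default 1.3).
#' @param bead_mass Monomer mass, g/mol (default 132.1, a pentose unit).
#' @param bond_length Bead-bead bond length, nm.
#' @param bead_radius Bead van der Waals radius, nm (used by surface-area
#'   analysis and self-avoidance).
#' @param min_separation Minimum distance between non-bonded beads, nm.
#' @param hydroxyls_per_bead Number of hydroxyl (O-H) decorations per bead
#'   (default 0); decorated beads can donate/accept hydrogen bonds.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A [configuration()] with zero moisture content.
#' @export
generate_polymer_configuration <- function(n_chains, beads_per_chain,
                                           target_density = 1.3,
                                           bead_mass = 132.1,
                                           bond_length = 0.5,
                                           bead_radius = 0.25,
                                           min_separation = 0.3,
                                           hydroxyls_per_bead = 0L,
                                           seed = 1L) {
  stopifnot(n_chains >= 1, beads_per_chain >= 1, target_density > 0,
            bead_mass > 0, bond_length > 0, min_separation >= 0)
  n_beads <- n_chains * beads_per_chain
  mass_per_bead <- bead_mass +
    hydroxyls_per_bead * (ATOMIC_MASSES[["O"]] + ATOMIC_MASSES[["H"]])
  total_mass <- n_beads * mass_per_bead
  volume <- total_mass * GPMOL_PER_NM3_TO_GCM3 / target_density  # nm^3
  edge <- volume^(1 / 3)
  box <- new_box(rep(edge, 3))
  # hard-sphere feasibility: random close packing of min_separation spheres
  packing <- n_beads * (4 / 3) * pi * (min_separation / 2)^3 / volume
  if (packing > 0.64) {
    stop(sprintf(paste0("packing infeasible: target density %.3g g/cm^3 ",
                        "implies bead packing fraction %.2f > 0.64 at ",
                        "min_separation %.3g nm"),
                 target_density, packing, min_separation))
  }
  withr::with_seed(seed, {
    pos <- matrix(NA_real_, n_beads, 3)
    placed <- 0L
    for (chain in seq_len(n_chains)) {
      for (b in seq_len(beads_per_chain)) {
        ok <- FALSE
        for (try in seq_len(2000L)) {
          cand <- if (b == 1L) stats::runif(3, 0, edge) else
            pos[placed, ] + bond_length * drop(random_unit_vectors(1L))
          cand <- (cand %% edge)
          if (placed > 0L) {
            dmin <- min(sqrt(rowSums(
              min_image_disp(pos[seq_len(placed), , drop = FALSE], cand,
                             box)^2)))
            # the previous bead along the chain sits at bond_length < min_sep
            lim <- if (b == 1L) min_separation else
              min(min_separation, bond_length)
            if (dmin < lim - 1e-12) next
          }
          pos[placed + 1L, ] <- cand
          placed <- placed + 1L
          ok <- TRUE
          break
        }
        if (!ok) stop("packing infeasible: could not place bead ", b,
                      " of chain ", chain, " after 2000 attempts")
      }
    }
    chain_id <- rep(seq_len(n_chains), each = beads_per_chain)
    atoms <- atom_table(pos, "polymer", "C", chain_id,
                        mass = bead_mass, vdw_radius = bead_radius)
    if (hydroxyls_per_bead > 0L) {
      for (h in seq_len(hydroxyls_per_bead)) {
        u <- random_unit_vectors(n_beads)
        opos <- pos + (bead_radius + 0.05) * u
        hpos <- opos + 0.1 * random_unit_vectors(n_beads)
        oat <- atom_table(opos, "polymer", "O", chain_id)
        hat <- atom_table(hpos, "polymer", "H", chain_id)
        # hydroxyl mass is part of bead_mass accounting only when decorated
        atoms <- rbind(atoms, oat, hat)
      }
    }
    configuration(atoms, box)
  })
}

#' Hydrate a polymer configuration with a prescribed shell structure
#'
#' Inserts `round(m * polymer_mass / 18.015)` water molecules. For each
#' molecule the nearest-polymer-atom distance is drawn once from the shell
#' mixture (truncated below `d_min`); candidate oxygen positions at that
#' radius around random polymer anchor atoms are then rejection-sampled until
#' no other polymer atom lies closer, so the realized nearest-distance
#' distribution equals the requested truncated mixture. Draws that the
#' realized geometry cannot host within `max_tries` candidates are redrawn
#' and counted in `attr(cfg, "resampled")`.
#'
#' @param polymer A dry [configuration()].
#' @param m Target moisture content (mass ratio, >= 0).
#' @param shells A [shell_mixture()].
#' @param seed Integer seed.
#' @param d_min Contact (exclusion) distance to polymer atoms, nm.
#' @param max_tries Candidate positions per distance draw before redrawing.
#' @return A [configuration()] at moisture content m (within one molecule's
#'   mass); attribute `resampled` counts redrawn distances.
#' @export
generate_hydrated_configuration <- function(polymer, m,
                                            shells = shell_mixture(),
                                            seed = 1L, d_min = 0.15,
                                            max_tries = 1000L) {
  stopifnot(inherits(polymer, "pw_config"), m >= 0)
  if (m == 0) return(polymer)
  a <- polymer$atoms
  poly_rows <- a$role == "polymer"
  if (!any(poly_rows)) stop("polymer configuration has no polymer atoms")
  ppos <- as.matrix(a[poly_rows, c("x", "y", "z")])
  mp <- sum(a$mass[poly_rows])
  n_w <- round(m * mp / WATER_MOLAR_MASS)
  if (n_w == 0) return(polymer)
  box <- polymer$box
  withr::with_seed(seed, {
    opos <- matrix(NA_real_, n_w, 3)
    resampled <- 0L
    batch <- 64L
    for (i in seq_len(n_w)) {
      placed <- FALSE
      while (!placed) {
        dstar <- sample_shell_mixture(1L, shells, d_min)
        tries <- 0L
        while (tries < max_tries) {
          k <- min(batch, max_tries - tries)
          anchors <- ppos[sample.int(nrow(ppos), k, replace = TRUE), ,
                          drop = FALSE]
          cand <- anchors + dstar * random_unit_vectors(k)
          cand <- wrap_coords(cand, box)
          dmin <- apply(min_image_cross_dist(cand, ppos, box), 1, min)
          hit <- which(dmin >= dstar - 1e-9)[1]
          if (!is.na(hit)) {
            opos[i, ] <- cand[hit, ]
            placed <- TRUE
            break
          }
          tries <- tries + k
        }
        if (!placed) resampled <- resampled + 1L
      }
    }
    # rigid SPC-like geometry: O-H 0.1 nm, H-O-H 104.5 degrees, random
    # orientation
    theta <- 104.5 * pi / 180
    u1 <- random_unit_vectors(n_w)
    aux <- random_unit_vectors(n_w)
    perp <- aux - u1 * rowSums(aux * u1)
    perp <- perp / sqrt(rowSums(perp^2))
    u2 <- cos(theta) * u1 + sin(theta) * perp
    h1 <- opos + 0.1 * u1
    h2 <- opos + 0.1 * u2
    mol0 <- max(a$molecule_id)
    wat <- rbind(
      atom_table(opos, "water_O", "O", mol0 + seq_len(n_w)),
      atom_table(h1, "water_H", "H", mol0 + seq_len(n_w)),
      atom_table(h2, "water_H", "H", mol0 + seq_len(n_w)))
    cfg <- configuration(rbind(a, wat), box,
                         frame_index = polymer$frame_index)
    if (resampled > 0) {
      warning(resampled, " shell-distance draws were geometrically ",
              "unachievable and were redrawn")
    }
    attr(cfg, "resampled") <- resampled
    cfg
  })
}

#' Layer volume-fraction schedule over a moisture grid
#'
#' Emulates a first adsorbed layer that holds (essentially all) the water
#' until it saturates at `m_sat`, after which all additional water goes to
#' the second layer. Below saturation the first-layer fraction follows a
#' scaled exponential approach `f_w1_max * (1 - exp(-m/m0))` with `m0`
#' chosen so 99% of `f_w1_max` is reached at `m_sat`, capped by the total
#' water volume fraction (the first layer can never hold more water than
#' exists). The total water volume fraction comes from incompressible mixing
#' of polymer at `polymer_density` with water at `water_molar_volume` per
#' molecule. By default `f_w1_max` is set to the total water volume fraction
#' at `m_sat`, which places the layer-1 saturation knee (and the onset of
#' rapid layer-2 growth) exactly at `m_sat`.
#'
#' @param m_grid Non-negative, strictly increasing moisture contents.
#' @param m_sat Saturation moisture content of the first layer (default 0.3).
#' @param f_w1_max Saturated first-layer volume fraction (0 < . < 1);
#'   default NULL: the total water volume fraction at `m_sat`.
#' @param water_molar_volume Volume per water molecule, nm^3 (default 0.0299,
#'   i.e. 18.015 g/mol at 1.0 g/cm^3).
#' @param polymer_density Dry polymer density, g/cm^3 (default 1.3).
#' @param uptake Shape of the total water volume fraction vs m:
#'   `"two_regime_linear"` (default) interpolates the incompressible-mixing
#'   fraction linearly between m = 0, `m_sat` and the grid end, so the
#'   emulated property curves have exactly the two-linear-regime structure
#'   the crossover analysis targets; `"incompressible"` uses the hyperbolic
#'   incompressible-mixing fraction pointwise (curved within regimes).
#' @return An object of class `fraction_schedule`: data frame with columns
#'   m, f_p, f_w1, f_w2.
#' @export
generate_fraction_schedule <- function(m_grid, m_sat = 0.3, f_w1_max = NULL,
                                       water_molar_volume = 0.0299,
                                       polymer_density = 1.3,
                                       uptake = c("two_regime_linear",
                                                  "incompressible")) {
  m_grid <- as.numeric(m_grid)
  uptake <- match.arg(uptake)
  if (any(m_grid < 0) || is.unsorted(m_grid, strictly = TRUE)) {
    stop("m_grid must be non-negative and strictly increasing")
  }
  v_w_specific <- water_molar_volume * AVOGADRO * 1e-21 / WATER_MOLAR_MASS
  # cm^3 of water per gram polymer; total water volume fraction at m:
  wtot_mix <- function(m) (m * v_w_specific) /
    (1 / polymer_density + m * v_w_specific)
  wtot <- if (uptake == "incompressible") wtot_mix else function(m) {
    anchors <- sort(unique(c(0, m_sat, max(m_grid, m_sat))))
    stats::approx(anchors, wtot_mix(anchors), xout = m, rule = 2)$y
  }
  f_wtot <- wtot(m_grid)
  if (is.null(f_w1_max)) f_w1_max <- wtot_mix(m_sat)
  if (f_w1_max <= 0 || f_w1_max >= 1) stop("f_w1_max must lie in (0, 1)")
  m0 <- m_sat / log(100)  # reaches 99% of f_w1_max at m_sat
  f_w1 <- ifelse(m_grid >= m_sat, f_w1_max,
                 f_w1_max * (1 - exp(-m_grid / m0)))
  f_w1 <- pmin(f_w1, f_wtot)
  f_w2 <- f_wtot - f_w1
  f_p <- 1 - f_w1 - f_w2
  if (any(f_w1 + f_w2 >= 1)) {
    stop("water volume fraction reaches 1 on the grid; unphysical schedule")
  }
  structure(data.frame(m = m_grid, f_p = f_p, f_w1 = f_w1, f_w2 = f_w2),
            class = c("fraction_schedule", "data.frame"))
}

#' Synthetic composite property curve over a fraction schedule
#'
#' Evaluates the chosen composite model at every grid point of the schedule
#' and adds independent zero-mean Gaussian noise.
#'
#' @param model_kind `"mixture"`, `"parallel"` or `"series"`.
#' @param X_p,X_w1,X_w2 Component property values (polymer, first and second
#'   water layer). The series model requires all strictly positive.
#' @param schedule A [generate_fraction_schedule()] result.
#' @param noise_sd Gaussian noise standard deviation, same units as X.
#' @param seed Integer seed.
#' @param property,units Optional labels carried on the curve.
#' @return A [property_curve()] with fractions attached.
#' @export
generate_property_curve <- function(model_kind, X_p, X_w1, X_w2, schedule,
                                    noise_sd = 0, seed = 1L,
                                    property = NULL, units = NULL) {
  model_kind <- match.arg(tolower(model_kind),
                          c("mixture", "parallel", "series"))
  vals <- composite_predict(model_kind, X_p, X_w1, X_w2,
                            schedule$f_p, schedule$f_w1, schedule$f_w2)
  if (noise_sd > 0) {
    vals <- withr::with_seed(seed,
                             vals + stats::rnorm(length(vals), 0, noise_sd))
  }
  property_curve(schedule$m, vals, fractions = schedule,
                 property = property, units = units)
}

#' Synthetic linear observable series
#'
#' y = slope * x + intercept + Gaussian noise; fixture generator for the
#' property estimators (box length vs temperature, enthalpy vs temperature,
#' stress vs strain, ...).
#'
#' @param slope,intercept Line parameters.
#' @param x_grid Abscissa grid (non-empty).
#' @param noise_sd Gaussian noise sd.
#' @param seed Integer seed.
#' @param kind Optional series kind label (see [observable_series()]).
#' @return An [observable_series()].
#' @export
generate_linear_series <- function(slope, intercept, x_grid, noise_sd = 0,
                                   seed = 1L, kind = "generic") {
  if (!length(x_grid)) stop("x_grid must be non-empty")
  y <- slope * x_grid + intercept
  if (noise_sd > 0) {
    y <- withr::with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  }
  observable_series(x_grid, y, kind = kind)
}
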