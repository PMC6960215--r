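# Fixture builders and independent oracles used across the suite. Everything
# is generated in code; no binary fixtures.

# A water molecule's three atoms at a given oxygen position with fixed
# orientation (H along +x and in the xy plane).
water_atoms <- function(o, mol_id) {
  th <- 104.5 * pi / 180
  xyz <- rbind(o,
               o + c(0.1, 0, 0),
               o + 0.1 * c(cos(th), sin(th), 0))
  atom_table(xyz, c("water_O", "water_H", "water_H"), c("O", "H", "H"),
             mol_id)
}

# Configuration with polymer bead atoms at `ppos` (rows) and water oxygens at
# `wpos` (rows); bead masses chosen so moisture contents are controllable.
bead_water_config <- function(ppos, wpos = NULL, box_len = 10,
                              bead_mass = 132.1, bead_radius = 0.25) {
  ppos <- matrix(ppos, ncol = 3)
  atoms <- atom_table(ppos, "polymer", "C", seq_len(nrow(ppos)),
                      mass = bead_mass, vdw_radius = bead_radius)
  if (!is.null(wpos)) {
    wpos <- matrix(wpos, ncol = 3)
    for (i in seq_len(nrow(wpos))) {
      atoms <- rbind(atoms,
                     water_atoms(wpos[i, ], nrow(ppos) + i))
    }
  }
  configuration(atoms, new_box(box_len))
}

# Random atomistic configuration with hydroxyl-bearing polymer fragments and
# water molecules, for hydrogen-bond oracle comparisons.
random_hbond_config <- function(n_waters, n_hydroxyls, box_len = 3,
                                seed = 1) {
  withr::with_seed(seed, {
    atoms <- NULL
    mol <- 0L
    for (i in seq_len(n_hydroxyls)) {
      mol <- mol + 1L
      c_pos <- runif(3, 0, box_len)
      o_pos <- c_pos + 0.14 * rand_unit()
      h_pos <- o_pos + 0.1 * rand_unit()
      frag <- atom_table(rbind(c_pos, o_pos, h_pos), "polymer",
                         c("C", "O", "H"), mol)
      atoms <- rbind(atoms, frag)
    }
    for (i in seq_len(n_waters)) {
      mol <- mol + 1L
      o <- runif(3, 0, box_len)
      th <- 104.5 * pi / 180
      u1 <- rand_unit()
      aux <- rand_unit()
      perp <- aux - sum(aux * u1) * u1
      perp <- perp / sqrt(sum(perp^2))
      u2 <- cos(th) * u1 + sin(th) * perp
      w <- atom_table(rbind(o, o + 0.1 * u1, o + 0.1 * u2),
                      c("water_O", "water_H", "water_H"), c("O", "H", "H"),
                      mol)
      atoms <- rbind(atoms, w)
    }
    configuration(atoms, new_box(box_len))
  })
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Brute-force hydrogen-bond oracle: loops over every (donor O-H, acceptor O)
# triple using only minimum_image_distance and explicit vector geometry.
oracle_hbonds <- function(config, criteria = hbond_criteria(),
                          donor_map = NULL) {
  a <- config$atoms
  box <- config$box
  if (is.null(donor_map)) donor_map <- infer_donor_map(config)
  iO <- which(a$element == "O")
  out <- list()
  mi_vec <- function(from, to) {
    d <- to - from
    L <- box$lengths
    w <- which(box$periodic)
    d[w] <- d[w] - L[w] * round(d[w] / L[w])
    d
  }
  for (k in seq_len(nrow(donor_map))) {
    dO <- donor_map$O[k]; dH <- donor_map$H[k]
    pO <- as.numeric(a[dO, c("x", "y", "z")])
    vH <- mi_vec(pO, as.numeric(a[dH, c("x", "y", "z")]))
    for (acc in iO) {
      if (acc == dO) next
      vA <- mi_vec(pO, as.numeric(a[acc, c("x", "y", "z")]))
      r <- sqrt(sum(vA^2))
      if (r >= criteria$r_max) next
      cosa <- sum(vA * vH) / (r * sqrt(sum(vH^2)))
      alpha <- acos(min(1, max(-1, cosa))) * 180 / pi
      if (alpha < criteria$alpha_max) {
        cls <- if (a$role[dO] == "polymer" && a$role[acc] == "polymer") {
          "polymer_polymer"
        } else if (a$role[dO] != "polymer" && a$role[acc] != "polymer") {
          "water_water"
        } else "polymer_water"
        out[[length(out) + 1L]] <- data.frame(
          donor_O = dO, donor_H = dH, acceptor_O = acc, pair_class = cls,
          r = r, alpha = alpha)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor_O = integer(), donor_H = integer(),
                      acceptor_O = integer(), pair_class = character(),
                      r = numeric(), alpha = numeric()))
  }
  do.call(rbind, out)
}

# Sort bond tables into a canonical order for comparison.
canon_bonds <- function(b) {
  b <- as.data.frame(b)[, c("donor_O", "donor_H", "acceptor_O",
                            "pair_class")]
  b[order(b$donor_O, b$donor_H, b$acceptor_O), , drop = FALSE] |>
    `rownames<-`(NULL)
}

# Independent dense-random-point rolling-ball area oracle (seeded Monte
# Carlo directions instead of the golden spiral).
oracle_sasa <- function(coords, radii, box, probe = 0.1, n_points = 4e4,
                        seed = 99) {
  coords <- matrix(coords, ncol = 3)
  R <- radii + probe
  withr::with_seed(seed, {
    dirs <- matrix(rnorm(3 * n_points), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    total <- 0
    for (i in seq_len(nrow(coords))) {
      pts <- sweep(dirs * R[i], 2, coords[i, ], "+")
      exposed <- rep(TRUE, n_points)
      for (j in seq_len(nrow(coords))) {
        if (j == i) next
        d <- sweep(pts, 2, coords[j, ])
        L <- box$lengths
        for (k in which(box$periodic)) {
          d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
        }
        exposed <- exposed & rowSums(d^2) >= R[j]^2
      }
      total <- total + 4 * pi * R[i]^2 * mean(exposed)
    }
    total
  })
}

# Small dry polymer shared by several structural tests (cheap to build).
tiny_polymer <- function(seed = 11) {
  generate_polymer_configuration(2, 30, seed = seed)
}
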