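# Polymer-water distance statistic, population histogram, double-Gaussian
# decomposition (DGD), layer assignment and layer volume fractions.

#' Nearest-polymer-atom distance of every water molecule
#'
#' For each water molecule, the minimum over polymer atoms of the
#' minimum-image distance from its oxygen. "Polymer atom" includes polymer
#' hydrogens by default (configurable to heavy atoms only).
#'
#' @param config A [configuration()] with at least one polymer atom.
#' @param heavy_only Exclude polymer hydrogens from the search (default
#'   FALSE).
#' @return Numeric vector, one distance (nm) per water molecule, ordered by
#'   molecule_id.
#' @export
polymer_water_distances <- function(config, heavy_only = FALSE) {
  a <- config$atoms
  poly <- a$role == "polymer"
  if (heavy_only) poly <- poly & a$element != "H"
  if (!any(poly)) stop("configuration has no polymer atoms")
  wo <- which(a$role == "water_O")
  if (!length(wo)) return(numeric(0))
  wo <- wo[order(a$molecule_id[wo])]
  ppos <- coords_of(config, which(poly))
  opos <- coords_of(config, wo)
  out <- numeric(length(wo))
  chunk <- max(1L, floor(2e6 / nrow(ppos)))
  for (s in seq(1L, length(wo), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(wo))
    d <- min_image_cross_dist(opos[idx, , drop = FALSE], ppos, config$box)
    out[idx] <- apply(d, 1, min)
  }
  out
}

#' Time-averaged water population histogram over polymer-water distance
#'
#' Counts water molecules per half-open distance bin \[lo, hi) from 0 to
#' `d_max`, averaged over frames.
#'
#' @param distances Numeric vector of per-water distances (nm) for a single
#'   frame, or a list of such vectors (one per frame).
#' @param bin_width Bin width, nm (default 0.01).
#' @param d_max Histogram range end, nm (default 2.0). Distances at or beyond
#'   `d_max` are excluded; the excluded fraction is reported in the
#'   `truncated_fraction` field and a warning is raised if everything was
#'   truncated.
#' @param m Optional moisture-content label.
#' @return An object of class `distance_histogram` with fields `bin_edges`,
#'   `bin_centers`, `population`, `m`, `n_frames`, `truncated_fraction`.
#' @export
population_histogram <- function(distances, bin_width = 0.01, d_max = 2.0,
                                 m = NA_real_) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (!is.list(distances)) distances <- list(distances)
  edges <- seq(0, d_max, by = bin_width)
  if (edges[length(edges)] < d_max) edges <- c(edges, d_max)
  counts <- matrix(0, length(distances), length(edges) - 1L)
  n_total <- 0; n_kept <- 0
  for (f in seq_along(distances)) {
    d <- distances[[f]]
    n_total <- n_total + length(d)
    d <- d[d >= 0 & d < d_max]
    n_kept <- n_kept + length(d)
    if (length(d)) {
      counts[f, ] <- tabulate(findInterval(d, edges), length(edges) - 1L)
    }
  }
  if (n_total > 0 && n_kept == 0) {
    warning("all distances lie at or beyond d_max; histogram is empty")
  }
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 population = colMeans(counts), m = m,
                 n_frames = length(distances),
                 truncated_fraction = if (n_total) 1 - n_kept / n_total else 0),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf(paste0("distance histogram: %d bins of %.3g nm, total ",
                     "population %.1f over %d frame(s)"),
              length(x$population), diff(x$bin_edges[1:2]),
              sum(x$population), x$n_frames))
  if (x$truncated_fraction > 0) {
    cat(sprintf(" (%.1f%% beyond range)", 100 * x$truncated_fraction))
  }
  cat("\n")
  invisible(x)
}

dgd_model <- function(x, amp1, mean1, sd1, amp2, mean2, sd2) {
  amp1 * exp(-(x - mean1)^2 / (2 * sd1^2)) +
    amp2 * exp(-(x - mean2)^2 / (2 * sd2^2))
}

default_dgd_init <- function(hist) {
  x <- hist$bin_centers; y <- hist$population
  i1 <- which.max(y)
  # second initial center: highest bin at least 4 bins away from the first
  far <- abs(seq_along(y) - i1) > 4
  i2 <- if (any(far & y > 0)) which(far)[which.max(y[far])] else
    min(i1 + 8L, length(y))
  list(amp1 = y[i1], mean1 = x[i1], sd1 = 0.05,
       amp2 = max(y[i2], 1e-3), mean2 = x[i2], sd2 = 0.1)
}

#' Double-Gaussian decomposition of a water population histogram
#'
#' Least-squares fit of `amp1*exp(-(d-mean1)^2/(2*sd1^2)) + amp2*...` to the
#' bin centers and raw (count) populations. Means are ordered ascending on
#' return; a vanishing or boundary-pinned second component is flagged
#' `degenerate`.
#'
#' @param hist A [population_histogram()] with at least 6 nonzero bins.
#' @param init Optional named list of starting values (amp1, mean1, sd1,
#'   amp2, mean2, sd2); defaults are peak-scan heuristics.
#' @return An object of class `dgd_fit` with fields amp1, mean1, sd1, amp2,
#'   mean2, sd2 (nm), rss, degenerate.
#' @export
fit_double_gaussian <- function(hist, init = NULL) {
  stopifnot(inherits(hist, "distance_histogram"))
  x <- hist$bin_centers; y <- hist$population
  if (sum(y > 0) < 6) stop("histogram must have at least 6 nonzero bins")
  st <- default_dgd_init(hist)
  if (!is.null(init)) st[names(init)] <- init
  lower <- c(amp1 = 0, mean1 = min(x), sd1 = 1e-4,
             amp2 = 0, mean2 = min(x), sd2 = 1e-4)
  upper <- c(amp1 = Inf, mean1 = max(x), sd1 = diff(range(x)),
             amp2 = Inf, mean2 = max(x), sd2 = diff(range(x)))
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ dgd_model(x, amp1, mean1, sd1, amp2, mean2, sd2),
      data = df, start = st, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop("double-Gaussian fit did not converge: ", conditionMessage(e),
           "\nstart values were: ",
           paste(names(st), signif(unlist(st), 4), sep = "=", collapse = ", "),
           call. = FALSE)
    })
  p <- as.list(coef(fit))
  # order components by mean
  if (p$mean2 < p$mean1) {
    p <- list(amp1 = p$amp2, mean1 = p$mean2, sd1 = p$sd2,
              amp2 = p$amp1, mean2 = p$mean1, sd2 = p$sd1)
  }
  tot <- sum(y)
  degenerate <- p$amp2 * p$sd2 < 1e-6 * max(1, p$amp1 * p$sd1) ||
    p$sd2 <= 2e-4 || p$sd1 <= 2e-4 || p$amp2 < 1e-9 * max(1, tot)
  structure(c(p, list(rss = sum(residuals(fit)^2), degenerate = degenerate)),
            class = "dgd_fit")
}

#' @export
print.dgd_fit <- function(x, ...) {
  cat(sprintf(paste0("double-Gaussian decomposition:\n  peak 1: center %.3f ",
                     "nm (%.2f A), sd %.3f nm, amp %.2f\n  peak 2: center ",
                     "%.3f nm (%.2f A), sd %.3f nm, amp %.2f\n  rss %.4g%s\n"),
              x$mean1, x$mean1 * 10, x$sd1, x$amp1,
              x$mean2, x$mean2 * 10, x$sd2, x$amp2, x$rss,
              if (x$degenerate) "  [second component degenerate]" else ""))
  invisible(x)
}

#' Assign water molecules to adsorbed layers
#'
#' Layer 1: d < cutoff_12; layer 2: cutoff_12 <= d < cutoff_2end; beyond:
#' d >= cutoff_2end. With per-frame distance lists, counts are time averages.
#'
#' @param distances Vector of per-water distances (nm) or list of per-frame
#'   vectors.
#' @param cutoff_12 First/second layer cutoff, nm (default 0.45, i.e. the
#'   4.5 Angstrom valley between the shells).
#' @param cutoff_2end Second-layer outer cutoff, nm (default 2.0).
#' @return Object of class `layer_partition` with time-averaged counts n_w1,
#'   n_w2, n_beyond and the cutoffs.
#' @export
assign_layers <- function(distances, cutoff_12 = 0.45, cutoff_2end = 2.0) {
  if (!(cutoff_12 > 0 && cutoff_12 < cutoff_2end)) {
    stop("need 0 < cutoff_12 < cutoff_2end")
  }
  if (!is.list(distances)) distances <- list(distances)
  cnt <- vapply(distances, function(d) {
    c(sum(d < cutoff_12), sum(d >= cutoff_12 & d < cutoff_2end),
      sum(d >= cutoff_2end))
  }, numeric(3))
  structure(list(n_w1 = mean(cnt[1, ]), n_w2 = mean(cnt[2, ]),
                 n_beyond = mean(cnt[3, ]),
                 cutoff_12 = cutoff_12, cutoff_2end = cutoff_2end,
                 n_frames = length(distances)),
            class = "layer_partition")
}

#' @export
print.layer_partition <- function(x, ...) {
  cat(sprintf(paste0("layer partition (cutoffs %.2f / %.2f nm): ",
                     "n_w1 = %.1f, n_w2 = %.1f, beyond = %.1f\n"),
              x$cutoff_12, x$cutoff_2end, x$n_w1, x$n_w2, x$n_beyond))
  invisible(x)
}

#' Layer volume fractions from a partition
#'
#' f_wi = n_wi * water_molar_volume / V; the polymer fraction closes the sum
#' to 1 exactly.
#'
#' @param partition An [assign_layers()] result (or a list with n_w1, n_w2).
#' @param box_volume System volume V, nm^3 (> 0).
#' @param water_molar_volume Volume per water molecule, nm^3 (default
#'   0.0299).
#' @return Named numeric vector (f_p, f_w1, f_w2), summing to 1.
#' @export
layer_volume_fractions <- function(partition, box_volume,
                                   water_molar_volume = 0.0299) {
  if (box_volume <= 0) stop("box_volume must be > 0")
  f_w1 <- partition$n_w1 * water_molar_volume / box_volume
  f_w2 <- partition$n_w2 * water_molar_volume / box_volume
  f_p <- 1 - f_w1 - f_w2
  if (f_p < 0) {
    stop("water volume exceeds the box volume: unphysical partition")
  }
  c(f_p = f_p, f_w1 = f_w1, f_w2 = f_w2)
}
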