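# Moisture-induced crossover detection: continuous two-segment linear fit
# with a grid-plus-refinement breakpoint search, residual-bootstrap
# confidence interval, and an explicit permutation decision rule for "no
# crossover".

two_segment_design <- function(m, psi, continuous = TRUE) {
  if (continuous) {
    cbind(1, m, pmax(m - psi, 0))
  } else {
    hi <- as.numeric(m > psi)
    cbind(1 - hi, (1 - hi) * m, hi, hi * m)
  }
}

two_segment_rss <- function(m, y, psi, continuous = TRUE) {
  X <- two_segment_design(m, psi, continuous)
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

fit_at_break <- function(m, y, psi, continuous = TRUE) {
  X <- two_segment_design(m, psi, continuous)
  fit <- lm.fit(X, y)
  b <- fit$coefficients
  if (continuous) {
    list(intercept_lo = b[1], slope_lo = b[2], slope_hi = b[2] + b[3],
         intercept_hi = b[1] - b[3] * psi,
         rss = sum(fit$residuals^2), fitted = fit$fitted.values)
  } else {
    list(intercept_lo = b[1] * 1, slope_lo = b[2], slope_hi = b[4],
         intercept_hi = b[3],
         rss = sum(fit$residuals^2), fitted = fit$fitted.values)
  }
}

best_breakpoint <- function(m, y, candidates, continuous, refine) {
  rss <- vapply(candidates, function(p) two_segment_rss(m, y, p, continuous),
                0)
  i <- which.min(rss)
  psi <- candidates[i]
  if (refine && length(candidates) > 1) {
    lo <- candidates[max(1, i - 1)]
    hi <- candidates[min(length(candidates), i + 1)]
    if (hi > lo) {
      opt <- optimize(function(p) two_segment_rss(m, y, p, continuous),
                      c(lo, hi), tol = 1e-10 * max(1, abs(hi)))
      if (opt$objective < rss[i]) psi <- opt$minimum
    }
  }
  psi
}

#' Two-segment piecewise-linear fit with breakpoint search
#'
#' Fits a continuous two-segment linear model to a property-vs-moisture
#' curve by exhaustive search over candidate breakpoints (the midpoints of
#' consecutive grid values inside `[m_min, m_max]`, each leaving at least 3
#' points per side), followed by local refinement of the best candidate. A
#' residual bootstrap gives a percentile confidence interval for the
#' breakpoint, and a permutation test of the two-segment improvement over a
#' single line decides the `verdict` ("crossover" / "no crossover").
#'
#' @param curve A [property_curve()] or data frame with columns m, value
#'   (>= 6 points).
#' @param m_min,m_max Breakpoint search bounds (defaults: data range).
#' @param continuous Enforce continuity at the breakpoint (default TRUE);
#'   FALSE fits two independent lines split at the breakpoint.
#' @param n_boot Residual-bootstrap replicates for the CI (default 199).
#' @param n_perm Permutation replicates for the decision rule (default 199).
#' @param alpha Significance level of the decision rule (default 0.05).
#' @param seed Integer seed for bootstrap and permutation.
#' @param refine Continuously refine the breakpoint inside the best grid
#'   interval (default TRUE).
#' @return Object of class `crossover_fit`: m_star, slope_lo, slope_hi,
#'   intercept_lo, rss, rss_one_segment, ci_m_star (length 2), p_value,
#'   verdict.
#' @export
fit_two_segment <- function(curve, m_min = NULL, m_max = NULL,
                            continuous = TRUE, n_boot = 199L,
                            n_perm = 199L, alpha = 0.05, seed = 1L,
                            refine = TRUE) {
  m <- curve$m; y <- curve$value
  ord <- order(m)
  m <- m[ord]; y <- y[ord]
  n <- length(m)
  if (n < 6) stop("two-segment fitting needs at least 6 points")
  if (is.null(m_min)) m_min <- min(m)
  if (is.null(m_max)) m_max <- max(m)
  if (!(m_min < m_max)) stop("m_min must be below m_max")
  mids <- (m[-1] + m[-n]) / 2
  ok <- vapply(mids, function(p) sum(m <= p) >= 3 && sum(m > p) >= 3,
               TRUE) & mids >= m_min & mids <= m_max
  candidates <- mids[ok]
  if (!length(candidates)) {
    stop("no candidate breakpoint leaves at least 3 points on both sides ",
         "within [m_min, m_max]")
  }
  psi <- best_breakpoint(m, y, candidates, continuous, refine)
  two <- fit_at_break(m, y, psi, continuous)
  one <- lm.fit(cbind(1, m), y)
  rss1 <- sum(one$residuals^2)

  res2 <- y - two$fitted
  boot_ci <- withr::with_seed(seed, {
    stars <- vapply(seq_len(n_boot), function(b) {
      yb <- two$fitted + sample(res2, n, replace = TRUE)
      best_breakpoint(m, yb, candidates, continuous, refine)
    }, 0)
    quantile(stars, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  })

  # decision rule: permutation of one-segment residuals under the null of a
  # single line; improvement statistic is the relative rss drop
  stat_obs <- (rss1 - two$rss) / rss1
  p_value <- withr::with_seed(seed + 1L, {
    stats_perm <- vapply(seq_len(n_perm), function(b) {
      yp <- one$fitted.values + sample(one$residuals)
      psi_p <- best_breakpoint(m, yp, candidates, continuous, refine)
      rss2p <- two_segment_rss(m, yp, psi_p, continuous)
      rss1p <- sum(lm.fit(cbind(1, m), yp)$residuals^2)
      (rss1p - rss2p) / rss1p
    }, 0)
    (1 + sum(stats_perm >= stat_obs)) / (n_perm + 1)
  })
  structure(list(m_star = psi, slope_lo = unname(two$slope_lo),
                 slope_hi = unname(two$slope_hi),
                 intercept_lo = unname(two$intercept_lo),
                 rss = two$rss, rss_one_segment = rss1,
                 ci_m_star = boot_ci, p_value = p_value,
                 verdict = if (p_value <= alpha) "crossover" else
                   "no crossover detected",
                 continuous = continuous, n = n),
            class = "crossover_fit")
}

#' @export
print.crossover_fit <- function(x, ...) {
  cat(sprintf(paste0("two-segment fit (%s): breakpoint m* = %.4f ",
                     "[%.4f, %.4f]\n  slopes %.4g -> %.4g, rss %.4g ",
                     "(one segment: %.4g)\n  %s (p = %.3f)\n"),
              if (x$continuous) "continuous" else "discontinuous",
              x$m_star, x$ci_m_star[1], x$ci_m_star[2],
              x$slope_lo, x$slope_hi, x$rss, x$rss_one_segment,
              x$verdict, x$p_value))
  invisible(x)
}
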