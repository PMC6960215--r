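# Pipeline orchestration: a validated parameter set with field defaults, a
# runner executing the analysis stages in dependency order over a synthetic
# study, and CSV/JSON writers that stamp every output with the parameters
# that produced it.

#' Pipeline run configuration
#'
#' All analysis parameters with their defaults; every output written by
#' [run_pipeline()] carries this parameter set in its metadata, so no
#' defaults are hidden.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param stages Stages to run, in dependency order, a subset of
#'   `c("generate", "hbonds", "layers", "contact_area", "props",
#'   "decompose", "crossover")`.
#' @param n_chains,beads_per_chain,target_density,bead_mass,hydroxyls_per_bead
#'   Dry-polymer generator parameters.
#' @param m_grid_structural Moisture grid for the structural stages
#'   (hydration, H-bonds, layers, contact area).
#' @param shells A [shell_mixture()].
#' @param r_max,alpha_max Hydrogen-bond criteria (nm, degrees).
#' @param cutoff_12,cutoff_2end Layer cutoffs, nm.
#' @param bin_width,d_max Histogram parameters, nm.
#' @param probe_radius,n_sphere_points Rolling-ball parameters.
#' @param water_molar_volume Volume per water molecule, nm^3.
#' @param m_grid_curves,m_sat,f_w1_max Fraction-schedule parameters for the
#'   property-curve stages.
#' @param table_params Named list of component property triples
#'   `c(X_p, X_w1, X_w2)` used to synthesize property curves; names must
#'   have defaults in [default_model_kind()].
#' @param curve_noise_frac Noise sd as a fraction of each curve's range.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir = "results/pipeline",
                       seed = 1L,
                       stages = c("generate", "hbonds", "layers",
                                  "contact_area", "props", "decompose",
                                  "crossover"),
                       n_chains = 3L, beads_per_chain = 40L,
                       target_density = 1.3, bead_mass = 132.1,
                       hydroxyls_per_bead = 1L,
                       m_grid_structural = seq(0.05, 0.5, by = 0.09),
                       shells = shell_mixture(),
                       r_max = 0.35, alpha_max = 30,
                       cutoff_12 = 0.45, cutoff_2end = 2.0,
                       bin_width = 0.01, d_max = 2.0,
                       probe_radius = 0.1, n_sphere_points = 240L,
                       water_molar_volume = 0.0299,
                       m_grid_curves = seq(0, 0.6, length.out = 25),
                       m_sat = 0.3, f_w1_max = 0.25,
                       table_params = list(
                         Q = c(3340, 1110, 2660),
                         CP = c(2.6, 4.6, 4.4),
                         K = c(5.9, 1.9, 1.5),
                         E = c(4.6, 1.1, 0.3),
                         G = c(1.9, 0.6, 0.06),
                         ALPHA = c(6.4e-5, 3.7e-4, 2.9e-4)),
                       curve_noise_frac = 0.01) {
  stages <- match.arg(stages, c("generate", "hbonds", "layers",
                                "contact_area", "props", "decompose",
                                "crossover"), several.ok = TRUE)
  if (cutoff_12 >= cutoff_2end) {
    stop("invalid configuration: cutoff_12 must be below cutoff_2end")
  }
  if (r_max <= 0 || alpha_max <= 0 || alpha_max >= 180) {
    stop("invalid configuration: hydrogen-bond criteria out of range")
  }
  if (bin_width <= 0 || d_max <= bin_width) {
    stop("invalid configuration: histogram binning out of range")
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
              n_chains = n_chains, beads_per_chain = beads_per_chain,
              target_density = target_density, bead_mass = bead_mass,
              hydroxyls_per_bead = hydroxyls_per_bead,
              m_grid_structural = m_grid_structural, shells = shells,
              r_max = r_max, alpha_max = alpha_max,
              cutoff_12 = cutoff_12, cutoff_2end = cutoff_2end,
              bin_width = bin_width, d_max = d_max,
              probe_radius = probe_radius,
              n_sphere_points = n_sphere_points,
              water_molar_volume = water_molar_volume,
              m_grid_curves = m_grid_curves, m_sat = m_sat,
              f_w1_max = f_w1_max, table_params = table_params,
              curve_noise_frac = curve_noise_frac)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; missing keys keep their
#' defaults. `shells` may be given as a named map (mean1, sd1, mean2, sd2,
#' weight1), `table_params` as a map of 3-element lists.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$shells)) raw$shells <- do.call(shell_mixture, raw$shells)
  if (!is.null(raw$table_params)) {
    raw$table_params <- lapply(raw$table_params, unlist)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

config_metadata <- function(config) {
  meta <- config
  meta$shells <- unclass(meta$shells)
  unclass(meta)
}

write_output_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

write_output_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the analysis pipeline on a synthetic study
#'
#' Executes the requested stages in dependency order: `generate` (dry
#' polymer + hydration series), `hbonds`, `layers`, `contact_area` over the
#' structural moisture grid, then `props` (synthetic observable series ->
#' property estimates), `decompose` (composite fits of synthetic property
#' curves) and `crossover` (two-segment fits). Writes CSV/JSON artifacts and
#' a provenance manifest into `config$out_dir`. Outputs are deterministic
#' given the seed (reruns are byte-identical).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  results <- list()
  manifest <- list(package = "hydrolayers",
                   version = as.character(utils::packageVersion("hydrolayers")),
                   parameters = config_metadata(config),
                   stages = list())
  log_stage <- function(name, files, t_start) {
    message(sprintf("[%s] done in %.1f s", name,
                    proc.time()[["elapsed"]] - t_start))
    manifest$stages[[name]] <<- list(status = "complete", outputs = files)
  }

  need_structures <- any(c("generate", "hbonds", "layers", "contact_area")
                         %in% config$stages)
  if (need_structures) {
    ts <- proc.time()[["elapsed"]]
    dry <- generate_polymer_configuration(
      config$n_chains, config$beads_per_chain, config$target_density,
      config$bead_mass, hydroxyls_per_bead = config$hydroxyls_per_bead,
      seed = config$seed)
    series <- lapply(seq_along(config$m_grid_structural), function(i) {
      suppressWarnings(generate_hydrated_configuration(
        dry, config$m_grid_structural[i], config$shells,
        seed = config$seed + i))
    })
    results$dry <- dry
    results$series <- series
    if ("generate" %in% config$stages) {
      f <- file.path(config$out_dir, "dry_polymer.gro")
      write_configuration(dry, f)
      log_stage("generate", basename(f), ts)
    }
  }

  V0 <- if (need_structures) box_volume(results$dry$box) else NA_real_

  if ("hbonds" %in% config$stages) {
    ts <- proc.time()[["elapsed"]]
    crit <- hbond_criteria(config$r_max, config$alpha_max)
    hb <- do.call(rbind, lapply(seq_along(results$series), function(i) {
      bonds <- detect_hbonds(results$series[[i]], crit)
      data.frame(m = config$m_grid_structural[i],
                 class = c("polymer_polymer", "polymer_water", "water_water"),
                 count = c(sum(bonds$pair_class == "polymer_polymer"),
                           sum(bonds$pair_class == "polymer_water"),
                           sum(bonds$pair_class == "water_water")))
    }))
    hb$density_per_nm3 <- hb$count / V0
    f <- file.path(config$out_dir, "hbond_density.csv")
    write_output_csv(hb, f)
    results$hbonds <- hb
    log_stage("hbonds", basename(f), ts)
  }

  if ("layers" %in% config$stages || "contact_area" %in% config$stages) {
    dists <- lapply(results$series, polymer_water_distances)
  }

  if ("layers" %in% config$stages) {
    ts <- proc.time()[["elapsed"]]
    part <- do.call(rbind, lapply(seq_along(dists), function(i) {
      p <- assign_layers(dists[[i]], config$cutoff_12, config$cutoff_2end)
      fr <- layer_volume_fractions(p, box_volume(results$series[[i]]$box),
                                   config$water_molar_volume)
      data.frame(m = config$m_grid_structural[i], n_w1 = p$n_w1,
                 n_w2 = p$n_w2, n_beyond = p$n_beyond,
                 f_p = fr[["f_p"]], f_w1 = fr[["f_w1"]],
                 f_w2 = fr[["f_w2"]])
    }))
    f1 <- file.path(config$out_dir, "layer_partition.csv")
    write_output_csv(part, f1)
    i_top <- length(dists)
    hist <- population_histogram(dists[[i_top]], config$bin_width,
                                 config$d_max,
                                 m = config$m_grid_structural[i_top])
    f2 <- file.path(config$out_dir, "population_histogram.csv")
    write_output_csv(data.frame(bin_center_nm = hist$bin_centers,
                                population = hist$population), f2)
    dgd <- fit_double_gaussian(hist)
    f3 <- file.path(config$out_dir, "dgd_fit.json")
    write_output_json(c(unclass(dgd),
                        list(m = hist$m, units = "nm",
                             parameters = config_metadata(config))), f3)
    results$partition <- part
    results$dgd <- dgd
    log_stage("layers", basename(c(f1, f2, f3)), ts)
  }

  if ("contact_area" %in% config$stages) {
    ts <- proc.time()[["elapsed"]]
    ca <- do.call(rbind, lapply(seq_along(results$series), function(i) {
      s <- contact_area(results$series[[i]], config$probe_radius,
                        config$n_sphere_points)
      data.frame(m = config$m_grid_structural[i],
                 A_polymer_nm2 = s$A_polymer, A_water_nm2 = s$A_water,
                 A_system_nm2 = s$A_system, A_contact_nm2 = s$A_contact)
    }))
    f <- file.path(config$out_dir, "contact_area.csv")
    write_output_csv(ca, f)
    results$contact <- ca
    log_stage("contact_area", basename(f), ts)
  }

  if (any(c("props", "decompose", "crossover") %in% config$stages)) {
    schedule <- generate_fraction_schedule(
      config$m_grid_curves, config$m_sat, config$f_w1_max,
      config$water_molar_volume)
    curves <- lapply(names(config$table_params), function(p) {
      tp <- config$table_params[[p]]
      kind <- default_model_kind(p)
      clean <- composite_predict(kind, tp[1], tp[2], tp[3],
                                 schedule$f_p, schedule$f_w1, schedule$f_w2)
      noise_sd <- config$curve_noise_frac * diff(range(clean))
      generate_property_curve(kind, tp[1], tp[2], tp[3], schedule,
                              noise_sd = noise_sd,
                              seed = config$seed + match(p, names(config$table_params)),
                              property = p)
    })
    names(curves) <- names(config$table_params)
    results$curves <- curves
  }

  if ("props" %in% config$stages) {
    ts <- proc.time()[["elapsed"]]
    # synthetic observable series consistent with the property curves at the
    # pure-polymer endpoint, run through the estimators
    pick <- function(name, i, default) {
      v <- config$table_params[[name]]
      if (is.null(v)) default else v[i]
    }
    alpha_true <- pick("ALPHA", 1, 6.4e-5)
    Tgrid <- seq(280, 320, by = 2)
    L <- generate_linear_series(5 * alpha_true, 5 * (1 - alpha_true * 300),
                                Tgrid, noise_sd = 0,
                                kind = "length_vs_temperature")
    cp_true <- pick("CP", 1, 2.6)
    H <- generate_linear_series(cp_true * 1e-3, 0, Tgrid, noise_sd = 0,
                                kind = "enthalpy_vs_temperature")
    E_true <- pick("E", 1, 4.6)
    eps <- seq(-0.02, 0.02, by = 0.002)
    ss <- generate_linear_series(E_true, 0, eps, noise_sd = 0,
                                 kind = "stress_vs_strain")
    props <- data.frame(
      property = c("ALPHA", "CP", "E"),
      value = c(thermal_expansion_coefficient(L, 300),
                heat_capacity(H, 1e-3),
                modulus_from_stress_strain(ss, 0.02)),
      units = c("1/K", "kJ/kg/K", "GPa"))
    f <- file.path(config$out_dir, "property_estimates.csv")
    write_output_csv(props, f)
    results$props <- props
    log_stage("props", basename(f), ts)
  }

  if ("decompose" %in% config$stages) {
    ts <- proc.time()[["elapsed"]]
    fits <- lapply(names(results$curves), function(p) {
      fit <- fit_composite(default_model_kind(p), results$curves[[p]])
      list(property = p, model = fit$model_kind, X_p = fit$X_p,
           X_w1 = fit$X_w1, X_w2 = fit$X_w2, se = as.list(fit$se),
           rss = fit$rss)
    })
    f <- file.path(config$out_dir, "composite_fits.json")
    write_output_json(list(fits = fits,
                           parameters = config_metadata(config)), f)
    results$composite_fits <- fits
    log_stage("decompose", basename(f), ts)
  }

  if ("crossover" %in% config$stages) {
    ts <- proc.time()[["elapsed"]]
    xo <- lapply(names(results$curves), function(p) {
      fit <- fit_two_segment(results$curves[[p]], seed = config$seed)
      list(property = p, m_star = fit$m_star,
           ci = as.numeric(fit$ci_m_star), slope_lo = fit$slope_lo,
           slope_hi = fit$slope_hi, p_value = fit$p_value,
           verdict = fit$verdict)
    })
    f <- file.path(config$out_dir, "crossover_fits.json")
    write_output_json(list(fits = xo,
                           parameters = config_metadata(config)), f)
    results$crossover <- xo
    log_stage("crossover", basename(f), ts)
  }

  manifest$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 2)
  write_output_json(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(list(results = results, manifest = manifest))
}
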