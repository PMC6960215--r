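#!/usr/bin/env Rscript
# Property estimators exercised on synthetic observable series with known
# truth: heat of adsorption from potential energies, thermal expansion from
# L(T), heat capacity from H(T), Young's modulus from stress-strain, and
# Poisson's ratio from paired strains. Truth values are chosen at the scale
# of the reference liquid-water / dry-polymer constants so the printed
# recoveries are recognizable.

suppressPackageStartupMessages(library(hydrolayers))
dir.create("results", showWarnings = FALSE)
SEED <- 7L

# heat of adsorption: 100 molecules bound by 4.07 kJ/mol against vapor
Q <- heat_of_adsorption(U_dry = -5.0e4,
                        U_hydrated = -5.0e4 + 100 * (-41) - 100 * 4.07,
                        n_water = 100, u_ref_vapor = -41)

# thermal expansion of a 5 nm box at the SPC-water-like 2.3e-4 1/K
Tg <- seq(280, 320, by = 2)
L_series <- generate_linear_series(5 * 2.3e-4, 5 * (1 - 2.3e-4 * 300), Tg,
                                   noise_sd = 5e-5, seed = SEED,
                                   kind = "length_vs_temperature")
alpha <- thermal_expansion_coefficient(L_series, T0 = 300)

# heat capacity of 1 g of liquid-water-like material (4.594 kJ/kg/K)
H_series <- generate_linear_series(4.594e-3, -1.2, Tg, noise_sd = 2e-4,
                                   seed = SEED,
                                   kind = "enthalpy_vs_temperature")
cp <- heat_capacity(H_series, mass = 1e-3)

# Young's modulus 2.5 GPa from a +/- 2% strain ramp
eps <- seq(-0.02, 0.02, by = 0.002)
ss <- generate_linear_series(2.5, 0, eps, noise_sd = 5e-4, seed = SEED,
                             kind = "stress_vs_strain")
E <- modulus_from_stress_strain(ss, max_strain = 0.02)

# Poisson's ratio 0.35 from paired axial/transverse strain
ax <- seq(0, 0.02, by = 0.002)
tv <- generate_linear_series(-0.35, 0, ax, noise_sd = 2e-4, seed = SEED)
nu <- poissons_ratio(ax, tv$y)

est <- data.frame(
  property = c("Q", "ALPHA", "CP", "E", "NU"),
  estimate = c(Q, alpha, cp, E, nu),
  truth = c(4.07 / 0.018015, 2.3e-4, 4.594, 2.5, 0.35),
  units = c("kJ/kg", "1/K", "kJ/kg/K", "GPa", "-"))
write.csv(est, "results/property_estimates.csv", row.names = FALSE,
          quote = FALSE)
print(est, digits = 4)
cat("max relative error:",
    sprintf("%.3g\n", max(abs(est$estimate / est$truth - 1))))
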