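---
title: "Hydration layering and the moisture-induced crossover: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration layering and the moisture-induced crossover: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrolayers)
```

# The problem

Hydrophilic biopolymers such as softwood xylan take up water, and their
thermodynamic and mechanical properties (heat of adsorption, heat capacity,
thermal expansion, elastic moduli, Poisson's ratio) change with moisture
content $m = m_\mathrm{water}/m_\mathrm{polymer}$. The striking observation
this package operationalizes is that all of these properties switch between
two roughly linear regimes at a common moisture content near 30 wt%, and
that the switch coincides with a structural event: the first adsorbed water
layer on the polymer surface saturates, and additional water begins
accumulating in a second, bulk-like layer. `hydrolayers` implements the
analysis chain that extracts this picture from atomistic configurations and
tabulated observables, together with a synthetic-data module that stands in
for molecular-dynamics trajectories.

# Data model and geometry

A configuration is an atom table (position in nm, role — polymer atom,
water oxygen or water hydrogen —, element, mass, van der Waals radius,
molecule id) plus an orthorhombic periodic box. Everything downstream uses
minimum-image distances; triclinic boxes are rejected rather than handled
approximately. One internal length unit (nm) is used throughout, with
Ångström only in reporting, to exclude silent factor-of-ten errors. Atomic
masses come from the standard IUPAC table (water: 18.015 g/mol) and default
van der Waals radii from the Bondi set, overridable per call; coarse-grained
beads carry explicit masses and radii. Post-processing uses wrapped
coordinates; whether the original trajectories would be wrapped or unwrapped
is immaterial for minimum-image statistics on orthorhombic boxes.

GRO (nm), PDB (Å, `CRYST1` box) and extended XYZ (Å, `Lattice=` comment)
files are read and written; roles are assigned from residue names
(`SOL`/`HOH`/`WAT`/... → water, the rest polymer). The coordinate formats
carry no masses, so bead masses must be re-supplied on read
(`mass_overrides`).

# Synthetic systems: what is emulated, and what is not

The generators reproduce the *statistical structure* the analyses consume,
not the physics that produced it:

- `generate_polymer_configuration()` grows self-avoiding random-walk bead
  chains (one bead per monomer, default 132.1 g/mol — a pentose unit) in a
  cubic box whose edge is chosen so density equals the target exactly
  (default 1.3 g/cm³, a typical dry xylan density). There is no force
  field, no equilibration; chains are geometrically plausible, nothing more.
- `generate_hydrated_configuration()` inserts
  $N_w = \mathrm{round}(m\,M_p/18.015)$ water molecules. For each molecule
  the nearest-polymer-atom distance $d^*$ is drawn **once** from a
  two-Gaussian shell mixture (defaults: 0.28/0.05 nm and 0.56/0.15 nm,
  first-shell weight 0.6, truncated below the 0.15 nm contact distance);
  candidate positions at radius $d^*$ around random polymer anchor atoms
  are then rejected until no other polymer atom lies closer. Because the
  distance is drawn once and only *positions* are resampled, the realized
  nearest-distance distribution equals the requested truncated mixture
  exactly; rejecting distances instead would deplete the far tail (large
  distances are geometrically harder to host in a dense matrix) and bias
  the fitted peak centers. Draws that remain unplaceable after 1000
  candidates (mostly mixture-tail distances beyond what a dense box can
  host) are redrawn, warned about, and counted in the `resampled`
  attribute — at 1.3 g/cm³ this affects roughly 1–2% of draws. Hydrogens
  are attached with the rigid water geometry (O–H 0.1 nm, 104.5°) at random
  orientation. Water–water excluded volume is *not* enforced; none of the
  implemented statistics depend on it.
- `generate_fraction_schedule()` builds the layer volume fractions
  $(f_p, f_{w1}, f_{w2})$, summing to 1, over a moisture grid. The total
  water volume fraction comes from incompressible mixing (polymer at 1.3
  g/cm³, water at 0.0299 nm³ per molecule, i.e. ~1 g/cm³ — the source data
  never state how fractions were computed, so simple volume bookkeeping is
  used). The first layer rises as $f_{w1,\max}(1 - e^{-m/m_0})$ with $m_0$
  set so 99% of the plateau is reached at the saturation point
  $m_\mathrm{sat}$ (default 0.3), capped by the total water fraction, and
  is constant above $m_\mathrm{sat}$; the second layer carries the rest.
  Two deliberate defaults shape this schedule:
  - $f_{w1,\max}$ defaults to the total water volume fraction at
    $m_\mathrm{sat}$. This encodes "the first layer holds essentially all
    water until it saturates", which places the onset of fast second-layer
    growth exactly at $m_\mathrm{sat}$ — the defining feature of the
    saturation picture. A smaller explicit $f_{w1,\max}$ moves the
    second-layer onset earlier, decoupling it from $m_\mathrm{sat}$.
  - the water-uptake curve is, by default, interpolated **linearly** in
    $m$ between 0, $m_\mathrm{sat}$ and the grid end
    (`uptake = "two_regime_linear"`), anchored to the incompressible-mixing
    values at those three points. The pointwise hyperbolic form
    (`uptake = "incompressible"`) is also available, but it is noticeably
    convex within each regime, and property curves built on it are curved
    *within* regimes — the two-segment fit then reports the curvature
    split, not the saturation knee (for the adsorption-heat parameters the
    noise-free breakpoint lands at 0.269 instead of 0.300). The reported
    phenomenon is two *linear* regimes meeting at the crossover, so the
    generator's default produces exactly that structure; this is a
    statement about what is being emulated, not a claim about which volume
    bookkeeping is physically truer.
- `generate_property_curve()` evaluates a composite model over a schedule
  and adds i.i.d. Gaussian noise; `generate_linear_series()` produces the
  observable series the property estimators consume.

All generators are deterministic given a seed (RNG state is restored
afterwards). What passing tests on these systems show is that the
*analysis* is correct and self-consistent; they cannot show that real MD
water obeys a two-Gaussian shell law or that real fractions saturate
sharply — those are inputs here, conclusions elsewhere.

# Hydrogen bonds

A hydrogen bond is a triple (donor O, its covalent H, acceptor O) with
$r_{\mathrm{OO}} < 0.35$ nm and $\alpha < 30^\circ$, where $\alpha$ is the
angle **at the donor oxygen** between the O→acceptor and O→H vectors. Many
trajectory tools use the hydrogen-centered angle; this package deliberately
does not — the donor-oxygen convention is the one the reference analysis
states. Donatable hydrogens are those covalently bound to an oxygen,
inferred geometrically (O–H < 0.12 nm) when no topology is given. Both
polymer and water oxygens may donate and accept; a donor H satisfying the
criteria with several acceptors contributes one bond per acceptor (no
exclusivity rule). Class densities divide the (time-averaged) count of
polymer–polymer, polymer–water or water–water bonds by the *dry* volume
$V_0$. The implementation prunes candidate pairs by distance before the
angle test; a brute-force all-triples oracle in the test suite checks exact
equivalence on systems up to 500 atoms.

# Hydration layers and the double-Gaussian decomposition

The layering coordinate is $d_{pw}$: for each water molecule, the minimum
over polymer atoms of the minimum-image distance from its oxygen. Polymer
hydrogens count as polymer atoms by default (`heavy_only = FALSE`). The
population histogram bins $d_{pw}$ in half-open 0.01 nm bins up to 2 nm,
averaged over frames; the truncated fraction beyond the range is reported,
never silently dropped. Bin width and range are defaults chosen to resolve
the 2.8/5.6 Å peaks and the 4.5 Å valley with smooth statistics — the
source analysis states neither.

The double-Gaussian decomposition fits
$a_1 e^{-(d-\mu_1)^2/2\sigma_1^2} + a_2 e^{-(d-\mu_2)^2/2\sigma_2^2}$
to the raw bin counts (not densities — the figure being emulated plots
population) by Levenberg–Marquardt least squares with non-negativity bounds,
peak-scan starting values, and means ordered ascending on return, so the
answer is invariant to permuted initial values. A second component pinned at
zero amplitude or vanishing width is flagged `degenerate` (the low-moisture
single-peak case). Non-convergence is an error carrying the start values.

Layers are assigned by fixed cutoffs: layer 1 below 0.45 nm, layer 2 from
0.45 to 2.0 nm, "beyond" above — the global 4.5 Å valley is used as a fixed
parameter rather than a per-dataset refit, matching the reference analysis;
layer volume fractions are count × molecular volume over box volume, closed
to 1 by the polymer fraction, with negative polymer volume an error.

# Surface and contact areas

Shrake–Rupley areas place `n_sphere_points` golden-spiral points on each
atom's expanded sphere (radius $r_\mathrm{vdW}$ + probe); a point is exposed
if outside every other atom's expanded sphere, with periodic images included
in burial tests (ignoring them inflates boundary-atom exposure). The probe
radius defaults to 0.1 nm — the choice being emulated — rather than the
conventional 0.14 nm water probe. The contact area is the defining identity
$A_\mathrm{contact} = A^\mathrm{polymer} + A^\mathrm{water} -
A^\mathrm{system}$, each term computed on its atom subset alone. The
golden-spiral construction is deterministic; 960 points per atom give
single-sphere areas exact to machine precision and cluster areas within 1%
of a 4×-denser sampling. The kernel is in C++ (quadratic neighbor search;
adequate for the system sizes this package targets).

# Property estimators

The estimators mirror standard definitions; the loading protocols of the
original measurements are not recoverable, so every slope is an ordinary
least-squares fit over the window the caller supplies:

- $Q = [U_\mathrm{dry} + N_w u_\mathrm{vap} - U_\mathrm{hyd}] /
  (N_w \cdot 0.018015\,\mathrm{kg/mol})$, referenced to isolated vapor so
  large-$m$ values approach the bulk latent-heat scale (~2260 kJ/kg);
  $u_\mathrm{vap}$ must be supplied explicitly, never defaulted.
- $\alpha_X = L'(T_0)/L(T_0)$ from one OLS line through $L(T)$;
- $C_p = H'(T)/\mathrm{mass}$;
- moduli as stress–strain slopes within $|\varepsilon| \le
  \varepsilon_\mathrm{max}$ (the same estimator serves uniaxial, volumetric
  and shear loadings);
- $\nu = -\mathrm{slope}(\varepsilon_\perp\ \mathrm{vs}\
  \varepsilon_\parallel)$.

# Composite models and their inversion

The three-component models treat the hydrated material as polymer + first
layer + second layer with volume fractions $f$: the mixture rule / parallel
model is the fraction-weighted arithmetic mean, the series model the
fraction-weighted harmonic mean. Mechanical moduli default to series, heat
of adsorption and heat capacity to mixture, thermal expansion to parallel —
the standard assignment for layered composites loaded normal to
(respectively along) the layers, overridable per fit.

Mixture/parallel inversion is linear least squares on the fraction design
(with inverse-variance weights when per-point uncertainties are supplied).
Series inversion first solves the *reciprocal* response — $1/X_c$ is linear
in $(1/X_p, 1/X_{w1}, 1/X_{w2})$ — in closed form, then polishes by bounded
(positive) minimization on the original scale; this removes any
initialization sensitivity. Standard errors come from the local quadratic
approximation $\sigma^2 (J^\top J)^{-1}$. A rank-deficient fraction design
(e.g. fractions that never vary independently across the grid) raises an
error naming the unidentifiable parameter rather than returning arbitrary
numbers. At zero noise all three model kinds round-trip generator truth to
optimizer precision; under noise the 3-standard-error coverage is validated
at ≥ 95% over seeded replicates.

# Crossover detection

The crossover is estimated by a continuous two-segment linear fit
$y = a + b\,m + c\,(m - \psi)_+$: for each candidate breakpoint (midpoints
of consecutive grid values leaving at least three points per side) the
model is linear and solved exactly; the best candidate is then refined
continuously inside its bracketing interval. Continuity is enforced by
default because the regimes being modeled visually meet; a discontinuous
two-line variant is available. Two decisions make the procedure explicit
where the original assessment was visual:

- uncertainty: a residual bootstrap (default 199 replicates) gives a
  percentile interval for $m^*$;
- existence: the verdict "crossover" requires the two-segment improvement
  in residual sum of squares over a single line to beat a permutation null
  (default 199 permutations, α = 0.05). A single noisy line is thus
  reported as "no crossover detected", not as a spurious breakpoint.

Nesting ($\mathrm{RSS}_2 \le \mathrm{RSS}_1$) and shift-equivariance of
$m^*$ are property-tested. Note that series-model property curves are
reciprocal-linear in $m$ and hence curved within regimes; a two-segment
*linear* fit applied to them reports a breakpoint that mixes curvature with
the saturation knee (the `analysis/06` driver shows this honestly for the
moduli, while mixture and parallel curves break at the saturation point).
The same two-segment machinery can be applied to hydrogen-bond density
curves; nothing in the method forces the H-bond plateau and the property
crossover to coincide.

# Problem sizes and numerical choices

The shipped analyses and tests use 2–5 chains of 30–100 beads (hundreds of
polymer atoms, up to ~2200 waters), 960 sphere points per atom (240–480 in
the quick drivers), 0.01 nm histogram bins, and 199 bootstrap/permutation
replicates — sizes at which every stage completes in seconds to about a
minute while keeping Monte-Carlo errors well below the tolerances being
asserted. Degenerate inputs fail loudly and early: empty atom sets,
non-finite coordinates, zero polymer mass, unphysical water volumes,
rank-deficient designs, breakpoints without three points per side.

# Known limitations

- The generator's shell mixture is moisture-independent; the structural
  hydration series emulates shell *shape*, not the gradual filling of the
  second shell (that schedule lives in the fraction generator, where the
  composite and crossover stages consume it).
- Bead chains have no chemistry; hydrogen-bond analyses on generated
  systems are only meaningful with hydroxyl decorations
  (`hydroxyls_per_bead ≥ 1`) or on real atomistic input.
- No analytic (arc-based) surface areas, no H-bond lifetimes, no water
  dynamics, no multi-breakpoint segmentation — all out of scope.
- XTC/TRR/DCD trajectories are not parsed; convert to multi-frame
  GRO/PDB/XYZ first.
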