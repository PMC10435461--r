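---
title: "Models and methods behind metaldyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaldyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaldyn)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the defaults that matter, and the places
where a genuine design choice had to be made.

## The setting

Two isomorphous square-planar complexes — Ni(II) and Cu(II) chelated by a
pair of dithiocarbamate ligands — are assessed as substrates of the
drug-metabolising enzyme CYP3A4. The assessment chains together several
otherwise independent analyses: electronic reactivity indices from
frontier-orbital energies, crystallographic similarity of the two
complexes, and molecular-dynamics-style analyses of the protein–substrate
system (deviation metrics, conformational state populations, interaction
energies, electric fields at the catalytic Cys–metal contact). The
package reimplements the analysis layer only: quantum-chemistry and MD
engines are upstream data sources, and their printed outputs (orbital
energies, cell constants, energy components) are consumed as inputs.

## Reactivity descriptors

All eight global descriptors derive from the HOMO and LUMO energies in eV:
IP $=-E_{HOMO}$, EA $=-E_{LUMO}$, hardness
$\eta = (E_{LUMO}-E_{HOMO})/2$, softness $S = 1/\eta$, chemical potential
$\mu = -(IP+EA)/2$, electrophilicity $\omega = \mu^2/2\eta$,
electronegativity $\chi = -\mu$. Two conventions needed fixing:

* The band gap written as $E_{HOMO}-E_{LUMO}$ is negative whenever the
  orbital ordering is sane, while reactivity tables print it positive. We
  store the signed value (`e_g_signed`) and report the magnitude (`e_g`).
* $\chi$ is reported in eV. A printed unit of eV$^{1/2}$ for
  electronegativity is dimensionally inconsistent with $\chi=-\mu$ and is
  treated as a typo.

Descriptors are computed from unrounded intermediates. Published tables
chain *rounded* values (e.g. an electrophilicity quoted from a rounded
$\mu$ and $\eta$), so the package's values can differ from printed ones by
a couple of hundredths of an eV; tests allow ±0.05 eV for exactly this
reason. A degenerate gap ($E_{HOMO}=E_{LUMO}$) makes hardness zero and
softness undefined and is an explicit error, not an NaN. Open-shell
species are handled the pragmatic way the field does when a SOMO is
reported: descriptors still come from (HOMO, LUMO) and the SOMO energy is
carried as annotation.

Second-order stabilization energies use
$E^{(2)} = q_i |F_{ij}|^2 / (\varepsilon_j - \varepsilon_i)$ with inputs
in hartree and output in kcal/mol (conversion 627.5095, fixed
project-wide along with 27.2114 eV/hartree and
$k_B = 0.0019872041$ kcal mol⁻¹ K⁻¹).

## Crystal metrics

The unit-cell similarity index $\pi = (a+b+c)/(a'+b'+c') - 1$ uses only
the orthogonalized edge lengths, as defined; angles are stored but do not
enter. $\pi = 0$ means predictably isomorphous. Because the index is
quoted unsigned in practice, `similarity_index()` reports both the signed
value and $|\pi|$ rounded to three decimals, plus a *hint* flag at
$|\pi| \le 0.01$. That cutoff is a reporting convenience — the literature
pins down only $\pi = 0$ — and is labelled as such.

Energy-framework totals combine four pairwise-interaction components
(electrostatic, polarization, dispersion, repulsion) as
$\sum_i k_i E_i$. The component scale factors are not always printed
alongside published totals; the CE–HF model constants
(1.019, 0.651, 0.901, 0.811) are the default, every report echoes the
factors actually used, and a config override exists. With the bundled
printed components (themselves rounded to 2 decimals) the scaled total
lands within 0.05 kcal/mol of the published −53.85.

## Trajectory metrics

Superposition is the closed-form Kabsch solution (SVD of the
cross-covariance with determinant correction), which tests verify against
a brute-force multi-start rotational search to 10⁻⁶ Å. Backbone
selection means atoms named N, CA, C. Coordinate RMSD (cRMSD) superposes
each frame on the reference before the RMS; distance RMSD (dRMSD) instead
compares all intra-selection pair distances and needs no superposition,
so it is invariant to per-frame rigid motions — the natural metric for a
ligand tumbling in a binding site. dRMSD defaults to heavy atoms
(hydrogen names excluded); the choice is a documented flag because
sources rarely state it.

RMSF is computed the standard way: two-pass alignment (to the first
frame, then to the resulting average structure), per-atom RMS about the
time-average position, averaged within residues, with a grand
mean ± sd across residues as the mobility summary. Published
per-residue averages of ~12–15 Å are far larger than anything an aligned
RMSF produces; whatever protocol generated them was not reconstructable,
so this package implements the aligned definition and does not attempt to
reproduce those numbers.

Interdomain features are the six centre-of-mass distances among exactly
four named residue regions (mass-weighted; unit masses when none are
given). The per-state summary follows the table convention in which the
"total average" row is the mean of the three selected pair means — this
reproduces published state totals of 20.5 Å and 22.4 Å exactly at one
decimal — while its ± is the sample standard deviation of those three
means (the published ± for that row is not reproducible from the printed
values; noted, not imitated). One required config entry has no default:
the B–B′ loop/B′ helix residue range is never printed in the source
material, only drawn, so the user must supply it.

## Collective variables

"PCA of the backbone RMSD" is ambiguous; the implementation takes the
conventional reading — PCA of superposed backbone Cartesian coordinates,
the choice consistent with cRMSD — and offers PCA of per-residue
deviation magnitudes behind `mode = "deviations"`. Covariance (not
correlation) PCA is the default since coordinates share units; the same
reasoning leaves the six interdomain distances unstandardised before LDA
by default, with a `scale` flag. Component signs are fixed by making each
component's largest-magnitude loading positive so repeated runs are
comparable.

LDA whitens with the pooled within-class covariance (Cholesky; if
singular, a ridge of $10^{-8}\times$ the mean diagonal is added and
logged) and takes the SVD of the whitened, weight-scaled class-mean
matrix, giving at most $n_{classes}-1$ informative directions. When true
labels are absent the intended pipeline order is mixture-model hard
assignment first, LDA second.

## The mixture state model

Frames projected to a low-dimensional CV space (two dimensions by
default) are modelled as a full-covariance Gaussian mixture fitted by EM:
k-means++-style seeding from the run seed, five restarts per candidate
component count, convergence when the log-likelihood change drops below
10⁻⁶ (cap 500 iterations), a 10⁻⁶ diagonal covariance floor, and model
selection by minimum BIC over `k_range` (the source material is silent on
selection; BIC is the conservative default). The free-energy landscape is
$G(x) = -k_B T \log \rho(x)$ at 300 K — the production simulation
temperature — shifted so the global minimum is zero; grid cells with
density below 10⁻¹² are flagged not-sampled rather than mapped to huge
finite energies. The default grid is 100 points per axis spanning the
data range plus 10%.

Core states are where this model earns its keep. For each component the
mixture density is profiled along the Mahalanobis radius from the
component mean (averaged over a fan of directions), and the first sign
change of the profile's second derivative — the density inflection —
sets that component's core threshold. A frame belongs to a core iff its
posterior for that component exceeds 0.5 *and* its mixture density meets
the threshold; everything else stays unassigned. For an isolated Gaussian
the inflection sits at Mahalanobis radius 1, so the core holds
$1-e^{-1/2} \approx 39.3\%$ of that component's mass in 2-D — which is
why total core populations sum to well under 100%, as state-population
tables in this field show. If no inflection is found (degenerate
profiles), the threshold falls back to the 60th density percentile of the
component's members, with a message.

State "pathways" here are energy orderings — states ranked by the free
energy of their density modes, ties broken by population then index —
not kinetics. A published pathway that mixes occupancy trends across
systems is not something this ordering claims to reproduce.

## Interaction energies and electric fields

The ligand–protein interaction is the pairwise sum of point-charge
Coulomb ($332.0637\, q_i q_j / r_{ij}$ kcal/mol) and Lennard-Jones
($4\epsilon[(\sigma/r)^{12}-(\sigma/r)^6]$, Lorentz–Berthelot combining)
terms over cross pairs within a 12 Å cutoff (mirroring the simulation
setup), uniform dielectric, no exclusions — the substrate shares no bonds
with the protein. One genuine conflict: the interaction energy is printed
in the source as $E_{elect} - E_{vdW}$, contrary to the conventional LIE
sum. The default combiner is `"sum"` (consistent with strongly negative
averages driven by two attractive terms); `"paper_eq11"` applies the
printed difference for literal fidelity. The choice is recorded on every
profile rather than silently corrected. Tightly/loosely bound frames are
the argmin/argmax of the per-frame total.

The electric field at a probe bond is the bare point-charge sum
$\vec E = K \sum_i q_i (\vec p - \vec r_i)/|\vec p-\vec r_i|^3$ with
$K = 1439.964$ MV Å² cm⁻¹ e⁻¹ (from $e/4\pi\varepsilon_0$, unit-tested),
projected onto the bond axis; positive values point from the first probe
atom to the second. Defaults that the source material leaves open, fixed
here and configurable: the evaluation point is the bond midpoint
(bond-mode convention of field analysis tools); the probe atoms and the
entire ligand are excluded from the sources, because the quantity of
interest is the *protein environment's* action on the metal–sulfur
contact; projections are averaged signed, not as magnitudes. No distance
cutoff is applied — fields decay as $r^{-2}$ and the full sum is cheap at
this scale. The per-residue decomposition is exactly additive by
construction, and residues with |mean| ≥ 7.5 MV/cm are ranked as highly
significant.

## The synthetic generator

The real study's trajectories are not deposited, so the package generates
its own ground truth; the generator is first-class, tested code.

The 2-D sampler integrates overdamped (Brownian) Langevin dynamics — the
full inertial equation adds nothing when only equilibrium statistics are
consumed — on a landscape built as a soft minimum of parabolic basins:
$U(x) = -\epsilon\log\sum_i e^{-V_i(x)/\epsilon}$,
$V_i = -d_i + \tfrac{1}{2}k_i|x-c_i|^2$, $k_i = d_i/w_i^2$, with a fixed
seam smoothing $\epsilon = 0.2$ kcal/mol. This form was chosen over a sum
of inverted Gaussians deliberately: each basin is exactly harmonic (so
the equipartition check $\mathrm{var} = k_B T/k$ has a clean closed
form), the landscape is globally confining (no flat background soaking up
Boltzmann mass), and for equal-stiffness wells the basin free-energy gap
equals the depth gap, making the two-well occupancy ratio
$e^{-\Delta G/k_B T}$ an honest target. Euler–Maruyama discretisation
biases the stationary variance by $+k\,\Delta t/2\gamma$; test settings
keep that below ~2%.

Bead-complex trajectories switch between anchor conformations by a
discrete Markov jump process (per-frame probability `switch_prob` of
redrawing the state from the stationary weights) with harmonic Gaussian
fluctuation about the active anchor. A jump process rather than true
barrier crossing gives *exact* per-frame state labels, which is the whole
point: clustering recovery can be scored against ground truth. What this
emulates is metastable conformational exchange with known populations;
what it does not emulate is everything else about real MD — solvent,
inertia, force-field physics, barrier-height kinetics, anisotropic
fluctuations. Passing tests therefore demonstrate that the analysis
machinery recovers known structure, not that the physics of any
particular protein is captured.

Every generator takes an explicit seed and is bit-reproducible; the
default seed 20230817 is recorded in output sidecars.

## Problem sizes and determinism

The shipped tests run at sizes chosen to make the statistical assertions
sharp without waste: 200,000 sampler steps for the 5%-tolerance
equipartition check; 300,000 steps for the two-well occupancy ratio
(giving a few dozen barrier crossings at a 2.6 $k_BT$ shallow-side
barrier); 5,000 points for mixture weight recovery (±0.05); 3,000-frame
bead trajectories for state-population recovery; 50,000 frames for
Markov-occupancy convergence (±0.03). The full pipeline re-run under one
seed reproduces every artifact checksum, which the suite asserts.

## Known limitations

* Absolute published MD numbers (state-population tables, −97/−87
  kcal/mol interaction averages, per-residue field magnitudes) require
  the original 1.5 μs trajectories and force-field parameterisation,
  which are not available; the package reproduces printed worked examples
  and statistical properties instead.
* The Coulomb/LJ terms are desk-scale explicit pair sums: no Ewald
  summation, reaction field, or polarisation.
* DCD reading assumes the little-endian X-PLOR/CHARMM dialect and fails
  loudly otherwise.
* The core-state construction assumes the CV density is reasonably
  mixture-like; heavily overlapping components fall back to percentile
  thresholds.
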