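---
title: "Multicomponent double-hybrid DFT in neodh: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicomponent double-hybrid DFT in neodh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`neodh` solves coupled Kohn–Sham equations for two fermionic species:
electrons, and a designated subset of protons treated quantum mechanically
in their own Gaussian basis.  The total energy separates into the external
interaction with the classical nuclei, the reference kinetic/Coulomb part,
the electronic exchange–correlation energy, and the electron–proton
correlation energy.  Two effective potentials follow variationally.  The
electronic one contains the usual kinetic, nuclear-attraction, Coulomb and
(hybrid) exchange–correlation terms, plus the attraction to the protonic
density and the electron-side electron–proton correlation potential.  The
protonic one contains the mass-scaled kinetic term, *repulsion* from the
positive classical nuclei, attraction to the electronic density, protonic
Coulomb with **full exact exchange** among the quantum protons, and the
proton-side correlation potential.  Three modelling commitments follow the
established multicomponent practice:

* quantum protons carry no point charge in any external potential — their
  charge acts only through their density; their fixed positions serve as
  basis centers (and electronic basis functions are also placed there);
* protons are same-spin fermions in a single determinant, one per orbital,
  with exact exchange `K^pp`; for one quantum proton `J^pp = K^pp`
  exactly, so the protonic mean field is self-interaction-free;
* no proton–proton correlation functional is included — its practical
  effect for chemically relevant systems is negligible and omitting it
  reduces cost.

Electron–proton correlation is an admixture of two terms.  The **epc-17.2**
functional is a local-density form
`E = -∫ ρe ρp / (a − b √(ρe ρp) + c ρe ρp) dr` with `(a, b, c) =
(2.35, 2.4, 6.6)`; the denominator is positive for all admissible densities
because `b² < 4ac`, so the energy is never positive.  The **MP2-type**
term sums simultaneous electron (i→a) and proton (i′→a′) single
excitations coupled by the electron–proton Coulomb operator:
`E = 2 Σ |(ia|i′a′)|² / (εi − εa + εi′ − εa′)` for closed-shell electrons.
Pure-electronic or pure-protonic singles are omitted, as in standard
double-hybrid practice of discarding singles on Kohn–Sham references; the
equation's generic sum would admit them, but they are not Brillouin-zero
here only through the functional, and leaving them out keeps the term
strictly a simultaneous-excitation correlation.

The double-hybrid assemblies keep the parent electronic constants
untouched (B2PLYP `a_ex = 0.53, c_ec = 0.27`; DSD-PBEP86
`c_ex = 0.69, c_ec = 0.44, c_os = 0.52, c_ss = 0.22` with the DFT
correlation entering at weight `c_ec`; PBEQIDH `λ_ex = 3^{-1/3},
λ_ec = 1/3`) and tune only `{b_epc, c_epc}`.  Every energy component is
stored unweighted in an `EnergyBreakdown`, so assemblies are pure
arithmetic and admixture scans do not re-run the SCF.

# Self-consistency scheme

The solver alternates species subcycles — an electronic SCF at fixed
protonic density, then a protonic SCF at fixed electronic density — inside
an outer loop, which matches the robust behaviour of alternating schemes
for this weakly coupled pair of problems.  Convergence thresholds are
1e-8 Eh on the energy and 1e-5 a.u. on the density change and orbital
gradient for both species; the inner subcycles run at slightly tighter
density/gradient thresholds so the outer test is meaningful.  DIIS keeps
the last 10 Fock matrices and starts after the first iteration.  The
orthogonalizer prunes overlap eigenvalues below 1e-10 (relative), which is
what makes the heavily overlapping even-tempered sets usable.

Two choices were genuinely open:

* **Which epc potential enters the SCF.**  The `b_epc`-scaled potential is
  used during the iterations, mirroring how double hybrids include the
  scaled DFT correlation potential self-consistently while the MP2-type
  term stays strictly post-SCF.  The unscaled alternative changes the
  orbitals (and hence the MP2-ep term) only at second order in
  `1 − b_epc`; for `b_epc ≈ 0.8` the effect on relative energies is far
  below the method's accuracy.
* **Initial guesses.**  The electronic guess is the converged
  single-component density with the quantum protons as classical
  hydrogens (falling back to a superposition of fractional-occupation
  atomic densities, then to the bare core).  The protonic guess
  diagonalizes the protonic core Hamiltonian *plus* the static attraction
  to the guess electronic density — the bare protonic core alone is purely
  repulsive and therefore unbound, so the plain core guess would start
  from an absurd density.

# Integrals, grids, and functionals

All integrals come from a McMurchie–Davidson engine over contracted
spherical Gaussians (l ≤ 4): Boys-function-based one-electron and
two-particle kernels, Schwarz screening, conventional 4-index tensors for
both species and the mixed electron–proton block, and optional 3-index
density-fitted tensors sharing one Coulomb metric (the mixed block uses
the union of the electronic and protonic fitting sets; the protonic
fitting default is the even-tempered 10s10p10d10f sequence spanning
2√2–64).

The quadrature grid is a Treutler–Ahlrichs M4 radial mapping with
Gauss–Chebyshev nodes and a Gauss–Legendre × trapezoidal spherical product
rule (exact through spherical-harmonic degree 2·nθ − 1), Becke-partitioned
with Bragg-radius size adjustment.  Quantum protons are grid centers of
their own with three deliberate differences: a *larger* partition radius
(1.5 bohr), a compressed, denser radial mapping, and a higher angular
order.  The larger radius is the important one: the protonic density is
extremely localized, and if a neighbouring heavy-atom cell owns part of its
tail, that cell's spherical grid (centered elsewhere) resolves the sharp
off-center feature poorly.  With these settings the converged electronic
and protonic densities integrate to their particle counts to ~1e-7 on the
default level-3 grid.  The product-rule grid is not exactly rotationally
invariant (no angular rule of finite order is); total energies move by
≲1e-6 Eh under rigid rotation, while rigid translation is exact.

Electronic functionals (Slater, VWN in both the VWN5 and RPA
parametrizations, B88, LYP, PBE exchange and correlation, PZ81+P86) are
implemented once as closed-shell energy densities `e(ρ, |∇ρ|²)`; the
potentials are Richardson-extrapolated central differences of that single
definition.  This trades a few floating-point digits (errors ~1e-10,
irrelevant at 1e-8 Eh convergence) for the guarantee that energies and
potentials can never drift apart — the classic failure mode of hand-coded
GGA derivatives.  The epc-17.2 potentials, by contrast, are analytic
(`∂e/∂g = −(a − b√g/2)/D²` with `g = ρeρp`), and are verified against
finite differences in the tests.  B3LYP follows the VWN5 convention; a
`b3lyp3` variant with the RPA fit is registered for comparisons with codes
using the other convention.

# Basis sets

Named reference sets (def2-TZVPP, def2-QZVPP-JKFIT, PB4-F2, PB6-F) are
distributed through external repositories, so the package cannot ship
them.  Instead it self-generates clearly labelled **synthetic surrogates**
and accepts user-supplied basis files (NWChem-style text) wherever a named
set is wanted:

* `synTZ` — triple-zeta quality: H 3s2p1d, C/N/O 5s3p2d1f.  Even-tempered
  s and p primitive sequences (12s/7p for C–O, chosen to span the core and
  valence ranges of first-row atoms) are contracted segmentally with
  1s/2s/2p coefficients taken from the package's own spherically averaged
  fractional-occupation atomic SCF in the uncontracted set; polarization
  exponents are fixed scalar choices near standard triple-zeta values.
* `synSV` — a faster split-valence set of the same construction, used by
  the fixtures.
* the protonic orbital surrogate — even-tempered 6s4p2d1f spanning the
  typical protonic exponent range 2–32; `protonic_basis("PB4-F2")`
  resolves to it (flagged `surrogate = TRUE`) unless the user supplies the
  real exponents from a file.

Because the surrogates span slightly different one-particle spaces than
the named sets, absolute energies and benchmark errors differ from
reference-set values; the package's own comparisons are therefore
internally consistent but not digit-for-digit transferable to results
computed with def2 bases.  This is the main caveat for the worked
reproductions below.

# Thermochemistry

Proton affinities are negative protonation enthalpies.  In the ideal-gas
picture the free proton loses `3/2 RT` of translational energy on binding
and the rotational change is negligible, so `PA = −ΔE_elec − ΔE_vib +
5/2 RT`.  The multicomponent route replaces the harmonic `ΔE_vib` by
quantizing the added proton — its anharmonic zero-point energy is part of
the NEO energy itself — and relies on the near-cancellation of the
classical-nuclei zero-point contributions between the protonated and
unprotonated species; consequently it adds no classical-vibration
correction.  `R` is pinned at 1.987204259e-3 kcal mol⁻¹ K⁻¹ and the
default temperature is 298.15 K (standard state; the experimental
reference values are standard-state numbers).  Unit conversions use
1 Eh = 627.5094740631 kcal/mol, pinned in one place.

Geometry optimization and harmonic frequency analysis are *not* features
of this package; they are consumed as numbers.  The shipped reference
inputs for the two small-molecule reproductions (geometries of NH3, NH4+,
NO2−, trans-HONO and the two `ΔE_vib` values) were computed once with the
package's own engine at B3LYP/synTZ — cyclic quadratic refinement in
symmetry internal coordinates for the geometries, full finite-difference
Cartesian Hessians (0.01 bohr displacements) with mass-weighted
projection of rigid-body modes for the frequencies — by
`inst/scripts/make_reference_inputs.R`.  The benchmark literature protocol
names an external optimizer at def2-TZVPP without stating the functional;
B3LYP-level geometries and frequencies are assumed here for both
reproductions.

# Bayesian parametrization of the admixture

The admixture objective (dataset RMSD against experimental proton
affinities) is minimized with Gaussian-process Bayesian optimization:
Matérn-5/2 kernel, constant prior mean, marginal-likelihood fitting of
length-scale and amplitude from five deterministic restarts, a 1e-8
diagonal jitter (the objective is deterministic), and plain expected
improvement (ξ = 0).  The budgets are 40 Latin-hypercube presamples plus
20 acquisitions in 2-D and 10 + 3 in 1-D, on [0, 1] bounds; in 1-D the
free parameter is `b_epc` with `c_epc = 1 − b_epc`.  Acquisition maximizes
EI on a dense candidate grid (2001 points in 1-D, 201×201 in 2-D) rather
than by gradient ascent — on a 1–2-D box this is effectively exact and
makes seeded runs bit-reproducible.  Objective values are cached on
points rounded to 1e-6, and failed evaluations are recorded and skipped.
Because the epc potential is `b`-scaled inside the SCF, an exact objective
evaluation at a new `b_epc` re-runs the NEO-SCF per molecule; the
`EnergyBreakdown` design also supports a frozen-orbital fast mode (one SCF
at a reference admixture, assembly-only scans), which is an approximation
and is labelled as such wherever used.

# What the fixtures emulate — and what they do not

The fixture generator supplies deterministic toy quantum-proton systems:
`h2_quantum` (H2 with one quantized proton), `nh4_quantum` (ammonium with
one quantized proton), `hcn_like` (a linear test structure; kept out of
every benchmark table), and `toy2x2`, a fully hand-set 2×2 integral bundle
whose coupled HF ground state is verified against an exhaustive
orbital-rotation scan.  They exercise every term of the model — coupled
Fock builders, protonic exchange, epc, both MP2 terms — at sizes where
independent oracles (closed-form Gaussian integrals, brute-force
excitation sums, finite differences) are exact.  They do **not** emulate
the electronic complexity of the benchmark molecules: no heteroatom lone
pairs competing with the protonation site, no anions with diffuse density,
no conformational freedom.  Passing fixture tests therefore validates the
machinery, not the chemistry; the small-molecule reproductions and any
full-scale benchmark require real geometries and the reference basis sets.

# Problem sizes and tolerances used in the test suite

The suite runs the toy fixtures at split-valence quality (synSV, grid
levels 2–3) and the two proton-affinity reproductions at synTZ/grid 3
(70–110 spherical AOs per molecule) — sizes chosen so the whole suite
exercises every code path, including the four benchmark single points, in
well under half an hour on one CPU.  Oracle comparisons assert at the
precision the oracle supports: 1e-9 Eh for the toy2x2 scan, 1e-8 for
brute-force MP2 sums, 1e-6 relative for finite-difference epc potentials,
1e-8 for the dense-solve GP check, three standard errors for the
Monte-Carlo EI check.

# Known limitations

* Spin-restricted closed-shell electronic references only; every benchmark
  species here is closed-shell, but radicals are out of reach.
* No analytic nuclear gradients — geometry work must go through external
  engines or finite differences.
* The D3(BJ) dispersion hook evaluates a pairwise C6/C8 correction only
  from a user-supplied coefficient table; the CN-interpolated reference
  C6 data of the published D3 model belong to external dispersion codes
  and are not shipped, so the default provider returns exactly zero.  For
  the protonation energies of the small reference molecules the omitted
  term is ~0.1–0.3 kcal/mol.
* Synthetic surrogate bases (above): internally consistent, not
  digit-for-digit comparable with def2-based literature values.
* The spherical product grid loses exact rotational invariance beyond
  ~1e-6 Eh; translation is exact.
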