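# neodh — multicomponent double-hybrid density functional theory

`neodh` is an R implementation of nuclear–electronic orbital (NEO)
Kohn–Sham theory in which selected protons are treated quantum mechanically
on the same footing as the electrons, with the electron–proton correlation
described by a tunable admixture of the epc-17.2 local-density functional
and a second-order Møller–Plesset (MP2) perturbative term evaluated on the
converged multicomponent orbitals.  It is aimed at method developers and
computational chemists who want a transparent, fully inspectable
implementation of the multicomponent double-hybrid machinery — from the
Gaussian integrals up to the proton-affinity benchmark statistics — rather
than a black-box production code.

## The model

The total multicomponent energy is decomposed as

    E[ρe, ρp] = E_ext[ρe, ρp] + E_ref[ρe, ρp] + E_exc[ρe] + E_epc[ρe, ρp]

where `ρe` and `ρp` are the electronic and protonic one-particle densities,
`E_ext` is the interaction with the classical nuclei, `E_ref` the
noninteracting kinetic energy plus all inter-particle Coulomb terms
(including full exact exchange `K^pp` among the quantum protons, which makes
a single proton exactly self-interaction-free), `E_exc` an ordinary
electronic exchange–correlation functional, and `E_epc` the electron–proton
correlation.  No proton–proton correlation functional is used.

The double-hybrid assemblies combine these with exact exchange and MP2-type
correlation, e.g. for NEO-B2PLYP:

    E = E_ext,ref + (1 − a_ex) E_x^DFT + a_ex E_x^HF
        + (1 − c_ec) E_c^DFT + c_ec E_c^MP2
        + b_epc E_epc^DFT + c_epc E_epc^MP2

with the electronic constants of the parent functionals (B2PLYP:
a_ex = 0.53, c_ec = 0.27; DSD-PBEP86: c_ex = 0.69, c_ec = 0.44,
c_os = 0.52, c_ss = 0.22; PBEQIDH: λ_ex = 3^(−1/3), λ_ec = 1/3) kept fixed,
and only the electron–proton admixture {b_epc, c_epc} treated as tunable.
`E_epc^MP2` is the second-order energy of simultaneous electron and proton
single excitations coupled by the electron–proton Coulomb operator.  The
registry defaults are the one-parameter optima b_epc/c_epc =
0.875/0.125 (NEO-B2PLYP), 0.806/0.194 (NEO-DSD-PBEP86) and 0.731/0.269
(NEO-PBEQIDH); an admixture of roughly 0.8:0.2 is a robust general choice.

The package contains, all self-contained:

* a McMurchie–Davidson Gaussian integral engine (s–g functions, spherical
  AOs, conventional and density-fitted two-particle tensors, mixed
  electron–proton blocks),
* restricted Kohn–Sham and coupled electron–proton SCF solvers with Pulay
  DIIS (thresholds 1e-8 Eh / 1e-5 a.u.),
* LDA/GGA functionals (Slater, VWN, B88, LYP, PBE, P86) and the epc-17.2
  electron–proton correlation functional with analytic potentials,
* spin-resolved electronic MP2 and the electron–proton MP2 term,
* proton-affinity thermochemistry with the embedded PA21 and test-set
  reference tables,
* Bayesian optimization of {b_epc, c_epc} (Matérn-5/2 Gaussian process,
  expected improvement, Latin hypercube presampling),
* voxel-based electronic density-difference analysis along X–H bond axes,
* a thin command-line interface (`inst/cli/neodh`).

Named reference basis sets (def2-TZVPP, PB4-F2, …) are distributed through
external repositories and are not shipped; the package generates documented
synthetic surrogates ("synTZ", "synSV", and an even-tempered protonic set)
and reads user-supplied basis files for the named sets.  Absolute energies
and benchmark errors computed with the surrogates therefore differ from
values obtained with the reference sets.

## Worked example

A hydrogen molecule with one of the two protons treated quantum
mechanically:

```r
library(neodh)

mol <- quantum_molecule("H", matrix(c(0, 0, 0), 1, 3),
                        quantum_protons = matrix(c(0, 0, 1.4), 1, 3))
res <- run_neo_scf(mol, basis_configuration(electronic = "synSV"),
                   functional = "neo-b2plyp")
print(res$breakdown)
#> EnergyBreakdown (Eh):
#>   E_ext_ref           -0.4455110313
#>   E_ex_hf             -0.6315203644
#>   E_xc_scf            -0.3247499444
#>   E_epc_dft           -0.0343943290
#>   E_disp               0.0000000000
#>   E_ex_dft            -0.6323386446
#>   E_ec_dft            -0.0377407964
#>   E_ec_mp2_os         -0.0319600464
#>   E_ec_mp2_ss         -0.0000000000
#>   E_epc_mp2           -0.0076920514
res$energy
#> [1] -1.144653
```

Every slot of the breakdown is unweighted, so any admixture can be
assembled without re-running the SCF: `assemble_energy(res$breakdown,
get_functional("neo-b2plyp", b_epc = 1, c_epc = 0))` gives the plain
NEO-DFT total for the same orbitals.  The total lies above the
clamped-proton B2PLYP energy of H2 (−1.1627 Eh at the same basis) by
roughly the anharmonic zero-point energy of the quantized proton, which is
the physics the multicomponent route builds in.  The electron–proton
correlation terms are both negative, the DFT part (−0.0342 Eh) about four
times the MP2 part (−0.0077 Eh) — the same ~0.8:0.2 balance the admixture
parametrization arrives at.

A proton affinity through the multicomponent route needs one conventional
calculation of the base and one NEO calculation of the protonated species:

```r
pa <- proton_affinity_neo(E_A = res_base$energy, E_AH_neo = res_neo$energy)
```

Dataset scoring and admixture optimization operate on energy tables (see
`benchmark_dataset()` and `optimize_admixture()`), so externally computed
energies can be fed straight into the statistics and parametrization
layers.

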