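---
title: "Methods: self-consistent field theory for ion binding in grafted ssDNA brushes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-consistent field theory for ion binding in grafted ssDNA brushes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Short single-stranded DNA oligomers tethered to a sensor surface are
polyelectrolytes: every nucleobase participates in acid–base equilibrium and
in counterion-binding reactions with the surrounding electrolyte. Divalent
Mg^2+^ in particular binds strongly, reverses the sign of the monomer charge
(A^−^ + Mg^2+^ ⇌ AMg^+^), and thereby reorganizes the whole tethered layer.
`brushscft` implements a one-dimensional self-consistent field theory (SCFT)
for this system: 12-mer chains of adenine (A) and guanine (G) monomers,
end-grafted at surface density σ~p~ (chains/nm²), immersed in a mixed
NaCl/MgCl~2~ bath at fixed bulk pH and temperature. The model resolves, layer
by layer along the surface normal, the polymer, water and ion volume
fractions, the local electrostatic potential, the local pH, and the chemical
state of every monomer.

## The model

The semi-grand free energy per unit area contains the conformational entropy
of the grafted chains, the translational entropy of all free species
(water, H^+^, OH^−^, Na^+^, Mg^2+^, Cl^−^), the mixing and standard-state
free energy of the monomer states, and the mean-field electrostatic energy.
Extremization under two constraints yields all working equations:

* **Packing (incompressibility).** In every layer the volume fractions of
  polymer and free species sum to one. The conjugate Lagrange field π(z)
  (units kT/nm³) acts as a local lateral pressure: every species of volume
  v is depleted by exp(−π v).
* **Electrostatics.** The potential ψ(z) (kT/e) obeys the discrete Poisson
  equation ε ψ'' = −ρ~q~ with a zero-field (Neumann) condition at the wall
  and ψ → 0 in the bulk. The dielectric constant enters through the Bjerrum
  length (0.714 nm at 298 K, ε~r~ = 78.5).

Free species follow Boltzmann profiles in both fields,
ρ~γ~(z) = ρ~γ~^b^ exp(−π v~γ~ − z~γ~ ψ). Each monomer type is a four-state
system — deprotonated (charged −e), protonated, Na-bound, Mg-bound (+e) —
governed by local mass action with dimensionless activities ρ(z)·v~w~:

f~iH~/f~i−~ = K⁰~iH~ ρ~H+~v~w~, and likewise for Na^+^ and Mg^2+^. The four
fractions are normalized in closed form, so the corresponding Lagrange
multipliers never appear as solver unknowns. Chain conformations α are
reweighted by their layer contacts,

P(α) ∝ exp[ −Σ~k~ n~i~(α;k) ( ln f~i−~(k) + π(k) v~i~ − ψ(k) ) ],

the standard charge-regulation form: layers where binding is strong
(small f~i−~) attract monomers, layers that are crowded (large π) or
electrostatically unfavourable repel them.

### Bound-ion volumes

A bound ion keeps its volume: the Mg-bound monomer occupies
v~mono~ + v~Mg~, and the reaction volume change in the mass-action
exponents is zero. This choice is not cosmetic. First, it is the only
volume bookkeeping under which the conformation weight above is exactly the
functional derivative of the free energy (with shared state volumes an
extra −π Σ~s~ f~is~ v~s~ term would appear in the weight). Second, it is
the mechanism of the re-entrant brush behaviour: at high grafting density,
binding more Mg^2+^ inflates the monomers, steric pressure rises, and the
chains stretch with *increasing* salt — the opposite of the dilute-brush
collapse. Both regimes are asserted in the test suite.

## Parameters

| parameter | default | units | origin |
|---|---|---|---|
| Mg^2+^ binding ΔG⁰ (A, G) | −32.1, −35.6 | kJ/mol | experimentally derived totals |
| pKa (A, G) | 3.5, 1.6 | — | literature monomer values |
| Na^+^ binding ΔG⁰ (A, G) | 0, 0 | kJ/mol | model choice, see below |
| v~w~ (also H^+^, OH^−^) | 0.030 | nm³ | standard for this theory family |
| v~Na~, v~Cl~ | 0.05 | nm³ | hydrated ion volumes |
| v~Mg~ | 0.18 | nm³ | hydrated ion volume |
| v~A~ = v~G~ | 0.30 | nm³ | coarse-grained nucleotide volume |
| ε~r~, T | 78.5, 298 | —, K | water at room temperature |
| grid | 100 layers × 0.3 nm | | discretization of the half-space |

**Standard states.** The experimental binding free energies and pKa values
refer to the molar standard state. The model's mass action uses activities
ρ·v~w~, whose standard state is one molecule per water volume (≈55.5 M at
v~w~ = 0.030 nm³). All six constants are therefore converted uniformly:
K⁰ = exp(−ΔG⁰/RT) / (0.6022 v~w~), with the pKa path identical
(K⁰ = 10^pKa^/(0.6022 v~w~)). The conversion lives in one function
(`assoc_constant_to_vw()`) so the convention can be swapped in one place.

**Na^+^ binding.** No measured Na–nucleobase association energy exists for
this system; only the *components* of the Mg^2+^ free energy are reported
(a −21 kJ/mol non-specific electrostatic part plus an 11–15 kJ/mol specific
part). Treating −21 kJ/mol as a Na association energy would make 10 mM Na^+^
bind most monomers already in bulk solution, which is inconsistent with the
strong Mg-free acidification of the dense brush (local pH ≈ 4.5) that this
very model family reports: strongly Na-neutralized chains cannot sustain the
negative potential that acidifies the layer. The default is therefore
ΔG⁰~Na~ = 0 kJ/mol — an association constant of 1 M⁻¹, the typical magnitude
of weak monovalent ion pairing — and it is configurable like every other
constant.

## The chain ensemble

Chains are coarse-grained to one bead per nucleotide connected by virtual
bonds (default 0.6 nm, the order of the ssDNA P–P virtual bond), with a
fixed internal bond angle (112°) and three rotational isomeric torsion
states per interior bond (trans 180°, gauche ±60°). None of these numbers
is a measured quantity for this chain; they are standard RIS conventions
and all are configurable. A 12-mer has 3⁹ = 19 683 torsion assignments;
each is swept with uniform random rigid-body rotations (uniform quaternion
sampling), conformations that cross the wall are rejected, and accepted
conformations are binned into layers, collapsing duplicate occupancy
vectors with multiplicities. Rotations sweep the *full* assignment set
before repeating, so a capped ensemble samples every torsion assignment as
evenly as possible.

Production runs use 2×10⁵ accepted conformations; the test suite uses a
documented reduced size of 3 000. Doubling the production ensemble changes
the polymer volume-fraction profile by about one percent in sup-norm
(asserted in the tests); at the reduced size the same comparison gives
several percent, which bounds the sampling error of CI-scale results.

What the generator deliberately does not emulate: intra-chain excluded
volume beyond wall rejection (inter-chain and intra-layer crowding is
carried entirely by the packing constraint), base stacking and secondary
structure, sequence-dependent geometry, and any lateral (x, y)
inhomogeneity. Tests passing on this ensemble therefore validate the field
theory given a physically plausible conformational prior, not the
conformational statistics of real ssDNA.

## Numerics

The unknowns are π(z) and ψ(z) on the layer centres (200 unknowns at the
default grid). Both fields are bulk-gauged: the exchange chemical
potentials are chosen so that flat zero fields reproduce the bulk
electrolyte exactly, which makes the bare reservoir an exact solution and
gives clean far-field behaviour. The stacked residual is

1. packing: φ~p~ + Σ~γ~ φ~γ~ − 1 per layer;
2. Poisson: ε(ψ~k−1~ − 2ψ~k~ + ψ~k+1~)/δ² + ρ~q~(z~k~), with a Neumann
   ghost node at the wall and a Dirichlet zero above the top layer.

It is solved by damped Newton iteration with an *analytic* Jacobian: the
polymer block is the covariance of layer occupancies over the conformation
ensemble, assembled from three small cross-product matrices per iteration,
and is verified against finite differences in the unit tests (a
finite-difference Jacobian remains available as `control$jacobian = "fd"`).
Steps use an Armijo backtracking line search, a ridge fallback for
ill-conditioned Jacobians, and a heavily damped fixed-mixing move if the
line search stalls. Convergence is declared at max-norm residual 1e−8.
Dense high-salt brushes are reached by geometric continuation in σ~p~
(quarter-decade rungs, warm starts, bisection of failed rungs). Boltzmann
exponents are clipped at ±500 during early iterations; the solution flags
whether clipping was ever active at the final state (it must not be).
Degenerate inputs are handled explicitly: σ~p~ = 0 solves in zero
iterations, collinear bonds (180° bond angle) skip the undefined torsion
frame, zero-salt baths simply zero the corresponding branches.

The semi-grand potential per unit area is evaluated in the same bulk gauge
(it vanishes for the bare reservoir) with the field-eliminated
electrostatic sign, making the solution a joint maximum over both fields.
This provides the independent oracle: on toy problems small enough to
optimize directly (≤3 layers, hand-written conformations), BFGS plus a
diagonal-curvature polish on *numeric* derivatives of the potential must
reproduce the Newton fields to 1e−6, which ties the residual equations to
the free energy they came from.

## Observables

* Bound ions per chain: δ Σ~k~ [ρ~A~ f~AMg~ + ρ~G~ f~GMg~]/σ~p~ — the exact
  monomer-counting form (equivalent to the volume-fraction form for equal
  monomer volumes).
* Deprotonated polymer fraction f~P−~(z): volume-share-weighted mean of the
  per-type charged fractions; undefined (NA) in layers without polymer.
* Local pH: −log10 of the local molar H^+^ concentration — the only
  definition consistent with "bulk pH 7" inputs.
* Brush height: first-moment height 2⟨z⟩~φ~; "inside the brush" means
  layers with φ~p~ above 1e−4 of its peak.

## Known limitations

The calculation is strictly one-dimensional and mean-field: lateral
microphase separation, grafting defects and ion–ion correlations beyond
the mean field are out of scope, as are Mg^2+^ hydration-shell
(solvent-mediated) binding pathways and any secondary-structure formation.
At low ionic strength (10 mM, Debye length ≈ 3 nm) the electrostatic tail
of a dense brush decays to only ~1e−4 of its contact value within the
fixed 30 nm box, so far-field closure figures of 1e−6 are achievable only
at the Mg-containing state points; this is a geometry property of the
fixed grid, not a solver tolerance. Local pH magnitudes in the dense-brush
regime are sensitive to the unprinted coarse-grained chain geometry and
reference volumes; the package reproduces the qualitative structure
(acidification without Mg^2+^, alkalinization with it, anion exclusion)
robustly, while peak values can differ from other parameterizations by a
few tenths of a pH unit.
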