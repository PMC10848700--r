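---
title: "Electron-density topology as a fidelity witness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron-density topology as a fidelity witness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

A quantum processor that prepares a molecular ground state does not hand
back a wavefunction; what can be measured efficiently is the one-particle
reduced density matrix (1-RDM), the matrix of expectation values
$D_{pq} = \sum_\sigma \langle a^\dagger_{p\sigma} a_{q\sigma} \rangle$ over
a set of molecular orbitals that are known exactly on a classical computer.
From the measured $D$ and the orbitals $\phi_p(\mathbf r)$ the electron
density follows as

$$\rho(\mathbf r) = \sum_{pq} D_{pq}\, \phi_p(\mathbf r)\, \phi_q(\mathbf r),$$

with the spin sum absorbed into $D$ (all systems handled here are
closed-shell singlets with one shared spatial orbital set, so physical
occupations lie in $[0,2]$).

The density is an experimentally accessible observable — it can also be
reconstructed from X-ray diffraction — which makes its *topological
features* natural candidates for validating a quantum computation when no
trustworthy total energy is available: positions and signatures of critical
points, densities and Laplacians at bond critical points, and atomic
partial charges from a Bader partition. densiwit implements this pipeline:
construct $\rho$ from a (possibly noisy) 1-RDM, mitigate the measurement
noise on $D$, analyse the topology, and compare the resulting feature set
against a trusted reference feature set (the *witness*), obtained here from
a near-exact conventional calculation.

## Noise on the 1-RDM and its mitigation

Measurement noise enters the pipeline only through $D$. Writing
$\varepsilon_{pq} = D_{pq} - D^{\mathrm{NF}}_{pq}$ for the elementwise error
against the noise-free matrix, two structural error classes matter:

* **diagonally symmetric errors** ($\varepsilon_{ij} = \varepsilon_{ji}$),
  produced by coherent/incoherent channel noise, which shift orbital
  occupations and can change the apparent electron number; and
* **asymmetric errors** ($\varepsilon_{ij} \neq \varepsilon_{ji}$), which —
  because the real and imaginary parts of $a^\dagger_i a_j$ and
  $a^\dagger_j a_i$ are measured through the same operator combinations —
  arise solely from finite sampling.

The package's two-step mitigation enforces the two exactly known properties
of the ideal $D$:

1. `symmetrize()` — hermiticity: replace each off-diagonal pair by its
   mean, $(D_{pq}+D_{qp})/2$. The diagonal, and hence the trace, is
   untouched.
2. `rescale_trace()` — particle number: multiply the *entire* matrix by
   $n_\mathrm{el}/\mathrm{Tr}(D)$. Diagonal and off-diagonal elements are
   deliberately subject to the same factor, because state preparation (not
   the extra measurement-basis rotations for off-diagonal elements)
   dominates the error budget, so all elements are assumed comparably
   damaged.

`mitigate()` applies them in that order; since rescaling preserves
symmetry, the composite is idempotent. The order is pinned for determinism
even though the two orders coincide for real data (a diagonal cannot be
asymmetric). Deliberately **not** included: any projection to a
positive-semidefinite or occupation-bounded matrix. N-representability
purification is a different research direction; this package studies the
raw effect of the two elementary constraints, including their documented
failure mode (see below).

Mitigation cannot help where the error is *noise imbalance*: if noise
redistributes occupation between orbitals that overlap differently with a
spatial region, the trace constraint can even push a local feature further
from the truth. The bundled Li2 system shows this: depolarizing-style noise
over-occupies the weakly-overlapping π and antibonding σ* orbitals at the
expense of the bonding σ that feeds the midbond non-nuclear attractor
(NNA); rescaling then *further* depresses the σ occupation, and the NNA
charge moves away from its noise-free value. The
`run_noise_experiment()` driver reproduces this qualitative behaviour.

## Synthetic noise channels

Real-hardware error processes are emulated at the 1-RDM level by three
seeded channels (`noise_spec()`):

* **depolarizing** $D' = (1-\lambda)D + \lambda I$ — drift toward the
  maximally mixed state; in the spin-summed spatial convention every
  orbital drifts toward occupation 1, so a low-filling active space
  *overcounts* electrons (the direction observed for simulated devices);
* **damping** $D' = (1-\lambda)D$ — uniform decay toward the empty state;
  *undercounts* (the direction observed on hardware);
* **shot** — i.i.d. Gaussian noise of standard deviation $1/\sqrt{M}$ on
  every entry *independently*, so $(p,q)$ and $(q,p)$ fluctuate
  independently; this is deliberately the only source of asymmetric error,
  mirroring the measurement analysis above. The Frobenius norm of the
  asymmetric part then scales as $1/\sqrt{M}$, which the test suite checks
  by regression over 100 seeds.

These channels are idealizations. They do not model readout error,
time-fluctuating noise, correlated errors between Pauli strings, or any
circuit structure; consequently the package reproduces hardware *error
directions* (over/undercounting, asymmetry onset) but makes no claim of
reproducing specific noisy values measured on named devices. All stochastic
operations take an explicit integer seed (default 0) and restore the global
RNG state.

## Density evaluation

`density_model()` symmetrizes the full-space $D$ exactly, diagonalizes it
once into natural orbitals, and keeps eigenpairs with $|n_k| > 10^{-14}$;
the density and its derivatives are then sums over natural orbitals,
$\rho = \sum_k n_k \psi_k^2$. Negative eigenvalues of a noisy, unpurified
$D$ are retained — $\rho$ may legitimately dip below zero for unphysical
inputs, and the topology code must see that density, not a sanitized one.

Basis functions are contracted Cartesian Gaussians up to $l = 3$, with the
real-solid-harmonic transformation applied for shells flagged spherical.
Values, gradients and Hessians are analytic (a polynomial-times-radial
product rule evaluated in compiled code); finite differences appear only in
test oracles. Contributions are screened when
$\alpha_{\min} r^2 > 60$ ($e^{-60} \approx 10^{-26}$, far below every
tolerance used). Everything internal is in Hartree atomic units; the only
unit conversion in the package is Angstrom-to-bohr at the XYZ boundary.

Grids are uniform and axis-aligned with default spacing 0.1 bohr and a
margin of 7 bohr beyond the farthest nucleus (8 bohr for the spatially
extended Li2, whose NNA basin is diffuse). The grid is anchored at the
bounding-box center with an even voxel count per dimension, so a symmetric
molecule is sampled exactly mirror-symmetrically and symmetry-equivalent
basins receive identical populations instead of inheriting a tie-breaking
artifact.

## Topological analysis

**Critical points.** Newton iteration with the analytic Hessian, from a
deterministic seed set (nuclei, atom-pair midpoints, atom-triple centroids)
plus 32 seeded random points within 3 bohr of each nucleus. Steps are
capped at 0.3 bohr; convergence requires $|\nabla\rho| \le 10^{-10}$;
duplicates within $10^{-4}$ bohr merge keeping the lower-gradient
candidate; points with $\rho < 10^{-10}$ are dropped. Classification uses
the signature $\kappa$ (sum of Hessian eigenvalue signs, with
$|\lambda| < 10^{-8}$ counting as zero and reducing the rank): $(3,-3)$
maxima split into `nuclear_max` within 0.2 bohr of a nucleus and `nna`
beyond it — Gaussian-basis maxima sit slightly off the nuclei, and 0.2 bohr
cleanly separates that offset from a genuine midbond attractor (about
2.5 bohr from either Li in Li2); $(3,-1)$ are bond, $(3,+1)$ ring,
$(3,+3)$ cage points. Rank-deficient points (found only in numerically
flat far-field regions of diffuse bases) are reported as `degenerate` and
excluded from the Poincare-Hopf bookkeeping, which the suite checks as
(maxima incl. NNAs) − (bonds) + (rings) − (cages) = 1 on every system.

**Basins and charges.** Space is partitioned on the grid; the zero-flux
interatomic surfaces are never constructed explicitly. Two integrators are
provided:

* `method = "weighted"` (default): Yu-Trinkle fractional flux — voxels are
  processed in descending density order and distribute weight to
  higher-density face neighbours in proportion to the density difference
  times facet area over distance. This was made the default after
  measurement, not taste: plain on-lattice ascent converges to a
  *systematically wrong* partition where the density is nearly flat,
  because discrete ascent paths are restricted to lattice directions. On
  the Li2 NNA basin (total relief between saddle and maximum is only 2.6%
  of $\rho$) the ascent method yields an NNA charge of −0.44 at 0.1, 0.07
  and 0.05 bohr alike, while the weighted method gives −0.60 to −0.61 —
  confirmed independently by re-assigning every boundary voxel through
  exact analytic-gradient path tracing (−0.61).
* `method = "ascent"`: near-grid steepest ascent over 26-connected
  neighbours (slope = density difference over distance, ties broken toward
  the lower linear voxel index, path compression to the root). Kept for
  its determinism and speed on compact basins.

Grid local maxima are matched to attractor critical points within 1.5 times
the spacing; an unmatched maximum with $\rho \ge 10^{-6}$ is appended as a
new attractor with a warning, while unmatched maxima below that floor are
discretization ripples on flat far-field plateaus (ubiquitous for diffuse
augmented bases) and their voxels stay unassigned — the total density so
discarded is orders of magnitude below the reporting precision. Basin
populations are Riemann sums $\sum \rho\,\Delta V$; charges are
$q = Z - N(\Omega)$ with $Z = 0$ for NNA basins; a warning is issued if
more than 1% of the integrated density ends up unassigned.

Partial charges at 0.1 bohr are converged to about 0.01 e for compact
systems; quantitative tables in the acceptance checks use 0.05 bohr, a
choice fixed by a convergence study (0.1 → 0.07 → 0.05 changes charges by
less than 0.01 e, and the 0.05 values agree with the exact path-tracing
oracle to 0.001–0.01 e).

**Comparing against grid-based reference tools.** Densities at critical
points are robust: interpolating a 0.1-bohr grid reproduces them to about
$10^{-4}$. Laplacians are not: a spline or finite-difference second
derivative on a grid of spacing $h$ carries an $O(h^2 \rho'''')$ bias that
reaches a few percent at bond critical points of compact molecules.
densiwit's Laplacians are analytic; when checking them against numbers
produced by cube-file pipelines, discrepancies of 0.01–0.3 atomic units at
sharply curved critical points should be attributed to the grid bias of
the reference, not to the analytic values. The flat Li2 NNA, where the
bias vanishes, is the instructive control: there grid-based and analytic
values coincide to $10^{-4}$.

## Witness comparison

`extract_features()` bundles the critical points, the charge table and the
electron count of one density model. `compare_features()` matches critical
points greedily by distance, only within the same type, with a 0.5 bohr
cutoff — loose enough for basis-set-induced CP shifts in these systems,
tight enough never to pair a bond point with an NNA region — and reports
signed deltas (test minus witness) per pair, per-basin charge deltas
matched by attached atom (NNA to NNA), and the electron-count delta, plus
the summary maxima max|Δρ|, max|Δq|, |Δn|. No single scalar fidelity
number is invented: the interesting information is precisely *which*
features degrade under noise, and a scalar would bury the Li2/HCN noise
imbalance stories that motivate the approach.

## Bundled systems and the generator

The `inst/extdata` bundles are committed text artifacts produced once by
`inst/scripts/make_fixtures.py` (pure numpy/scipy: McMurchie-Davidson
integrals, restricted Hartree-Fock with DIIS, determinant FCI) and pinned
by checksum. For each system the noise-free active-space 1-RDM is the
*exact diagonalization* ground state in the stated active space with a
frozen-core approximation — the idealization of a converged, noiseless
variational quantum solver:

| bundle | basis | active space | frozen/inactive | electrons |
|---|---|---|---|---|
| `h2_sto3g` | STO-3G | (2e, 2o) | none | 2 |
| `lih_sto3g` | STO-3G | (2e, 3o) σ-space | Li 1s | 4 |
| `li2_sto3g` | STO-3G | (2e, 4o) | 2 × Li 1s | 6 |
| `hcn_sto3g` | STO-3G | (4e, 4o) π/π* | 2 core + 3 valence σ | 14 |
| `hcn_631g` | 6-31G | (4e, 4o) π/π* | 2 core + 3 valence σ | 14 |
| `h2_witness_augccpvtz` | aug-cc-pVTZ | full FCI | none | 2 |

Geometries are literature equilibrium values (H2 0.7414 Å, LiH 1.5949 Å,
Li2 2.6729 Å, HCN r(CH) = 1.064 Å, r(CN) = 1.156 Å), recorded in each
bundle's metadata. The LiH active space is selected by σ character
(2σ/3σ/4σ) rather than by orbital energy: the energy-ordered choice would
split the degenerate π pair, breaking cylindrical symmetry and raising the
CASCI energy. The HCN active space is the two bonding π and two
antibonding π* orbitals, identified by their vanishing coefficients on
every axis-symmetric AO; this is also what makes HCN the axial
noise-invariance control — any perturbation confined to the active block
cannot change $\rho$ anywhere on the molecular axis, a property the suite
checks to $10^{-12}$. HCN ships in two bases at the same geometry so basis
effects on the topology can be separated from noise effects; the STO-3G
bundle is the benchmark default. For two electrons CCSD is exactly FCI, so
the H2 witness 1-RDM (full FCI/aug-cc-pVTZ) is identical to a
CCSD/aug-cc-pVTZ density by construction, with no relaxed/unrelaxed
ambiguity.

The generator validates itself: Hermite-integral recursions against known
closed forms and Hartree-Fock anchors, the FCI solver (energies *and*
1-RDMs) against a brute-force Jordan-Wigner matrix construction to machine
precision, and a variational containment check (CASCI energy never above
RHF) that guards the active-space transformation.

What the synthetic setup does *not* establish: behaviour on open-shell
systems, on ring/cage-rich topologies, under real correlated hardware
noise, or for experimentally (diffraction-) derived witnesses. Passing
tests here demonstrate the pipeline's correctness on closed-shell diatomics
and one linear triatomic with computed witnesses, no more.

## Problem sizes and runtime choices

The test suite runs critical-point searches on all six bundles, basin
integrations at 0.1–0.2 bohr routinely and 0.05 bohr for the quantitative
charge tables, shot-noise regressions over 100 seeds at
$M \in \{10^2, 10^4, 10^6\}$, and 100-point finite-difference sweeps per
fixture. The witness feature extraction uses 0.15 bohr spacing: its only
quantitative targets are bond-point values (analytic, grid-free) and the
symmetric hydrogen charges. These sizes keep a full run in a few minutes on
one CPU while leaving every quantitative claim at its converged value.

## Known limitations

* Restricted (closed-shell) orbital sets only; no UHF-style files.
* Angular momentum up to f; no g shells.
* Degenerate (rank < 3) critical points are reported but not resolved
  into their unstable manifolds; ring/cage-rich molecules are out of scope.
* No bond paths, interatomic surfaces, ellipticities, or energy densities;
  bond-CP connectivity is inferred from the two nearest atoms.
* The 1-RDM noise channels are uncorrelated idealizations; device-specific
  noisy values are reproduced in direction, not magnitude.
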