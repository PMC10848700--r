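# densiwit

Topological fidelity witnesses for quantum-computed electron densities.

## The problem

A quantum device (or a simulator of one) that prepares a molecular ground
state yields, through efficient O(n²) measurements, the one-particle
reduced density matrix (1-RDM) over a set of classically known molecular
orbitals. Combined with those orbitals, the 1-RDM defines the molecule's
electron density

ρ(**r**) = Σ_pq D_pq φ_p(**r**) φ_q(**r**)

(spin summed into D; restricted closed-shell orbitals throughout). The
density is also an experimental observable — reconstructible from X-ray
diffraction — which makes its *topological features* candidates for
validating quantum computations whose energies cannot be checked
classically: critical points of ρ (where ∇ρ = 0, classified by the
signature κ, the sum of the signs of the Hessian eigenvalues), the density
and Laplacian ∇²ρ at bond critical points (κ = −1), and atomic partial
charges q = Z − N(Ω) integrated over Bader basins Ω.

Measurement noise corrupts D. densiwit implements the 1-RDM-level
mitigation that enforces the two exactly known properties of the ideal
matrix — hermiticity, by averaging off-diagonal pairs
(D_pq + D_qp)/2, and particle number, by rescaling the whole matrix by
n_el / Tr(D) — together with synthetic noise channels (depolarizing,
damping, finite-sampling "shot" noise), a full analytic QTAIM toolchain
(critical-point search with exact gradients and Hessians, Yu–Trinkle
weighted basin integration, partial charges, non-nuclear attractors), and
feature-set comparison against a trusted reference density (the
"witness").

Bundled benchmark systems: H₂, LiH, Li₂ (STO-3G) and HCN (STO-3G and
6-31G) with frozen-core active-space exact-diagonalization 1-RDMs — active
spaces (2,2), (2,3), (2,4), (4,4) — plus a near-exact H₂ witness at
FCI/aug-cc-pVTZ (identical to CCSD for two electrons). I/O covers XYZ,
Molden, Gaussian cube, and a documented JSON bundle format for 1-RDMs with
active-space metadata.

## Worked example

Perturb the LiH active-space 1-RDM with an undercounting damping channel
plus finite-sampling noise, mitigate it, and analyse the resulting
density:

```r
library(densiwit)

fx    <- load_fixture("lih_sto3g")
noisy <- apply_noise(fx$rdm, noise_spec("damping", strength = 0.06))
noisy <- apply_noise(noisy, noise_spec("shot", shots = 8192, seed = 0))
mitigated <- mitigate(noisy)

sapply(list(noise_free = fx$rdm, noisy = noisy, mitigated = mitigated),
       function(r) sum(diag(embed_active(r)$matrix)))
#> noise_free      noisy  mitigated
#>     4.0000     3.8985     4.0000
```

The damped, sampled matrix has lost about 0.1 electrons; symmetrization
plus trace rescaling restores the exact total of 4. The topology of the
mitigated density:

```r
model <- density_model(fx$wavefunction, mitigated)
cps   <- find_cps(model)
cps[, c("z", "rho", "laplacian", "signature", "cp_type")]
#>            z     rho laplacian signature     cp_type
#> 1 -0.0003961 8.12454 -826.8514        -3 nuclear_max
#> 2  1.3371685 0.04308    0.1272        -1        bond
#> 3  2.9969197 0.32338   -6.1710        -3 nuclear_max

map <- assign_basins(model, default_grid(fx$atoms, 0.1, 7), cps = cps)
basin_charges(map, model)[, c("element", "Z", "population", "charge")]
#>   element Z population  charge
#> 1      Li 3      2.193  0.8070
#> 2       H 1      1.806 -0.8059
```

Two nuclear maxima and one bond critical point between them (κ = −1,
positive ∇²ρ = 0.127: a closed-shell/ionic contact), and strongly ionic
Li⁺H⁻ charges of ±0.81 — close to, but measurably shifted from, the
noise-free ±0.83 because this channel's occupation imbalance is not fully
repairable by the trace constraint. `run_noise_experiment()` packages this
loop (noise-free / noisy / mitigated feature sets, electron-count table,
difference fields) for any bundled system, and `compare_features()` scores
any of them against the witness.

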