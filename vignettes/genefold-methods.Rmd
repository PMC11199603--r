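---
title: "Transcription-coupled gene folding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcription-coupled gene folding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefold)
```

## Scope

`genefold` quantifies how RNA Pol II occupancy relates to the 3D folding of
genes, and models the relationship mechanistically. It has three layers:

1. **Genome scoring.** Distance-normalized (obs/exp) contact maps from binned
   chromosome-conformation-capture matrices; per-gene scores
   $IC = \sum_{i<j} c_{ij} / \binom{N}{2}$ (mean obs/exp over bin pairs in
   the gene body — intra-gene contact enrichment) and
   $IR = \sum_i p_i / N$ (mean Pol II track signal — a proxy for
   transcriptional activity); clustering of genes by $\log_2 IR$ and dyadic
   length bins; condition comparisons.
2. **Pile-up meta-gene analysis (PMGA).** Each gene's $3l \times 3l$ obs/exp
   neighborhood (body plus equal flanks) rescaled to a fixed $60 \times 60$
   pseudo-matrix by area-weighted averaging, oriented in the transcription
   forward direction, and averaged over a gene cluster; inter-gene
   ($30 \times 30$) and peak-pair variants; ChIP meta-gene profiles.
3. **Simulation.** A TASEP model of Pol II loading, initiation, elongation
   and unloading (optionally with a two-state bursting promoter), coupled to
   a kinetic Monte Carlo polymer: a self-avoiding semi-flexible chain on an
   FCC lattice with periodic boundaries, where Pol II-bound monomers attract
   each other with strength $E$ when on nearest-neighbor sites, subject to a
   valency cap on simultaneous partners.

A synthetic-data generator emulates the statistical structure the scoring
layers assume (power-law distance decay, implanted intra-gene enrichment,
TSS–TTS loops, promoter stripes, plateau-plus-peaks coverage tracks), so the
full pipeline is testable with known ground truth and no external downloads.

## The TASEP transcription model

A gene is $n$ monomers; site $i$ carries $s_i \in \{0,1\}$ (Pol II bound or
not). One Monte Carlo step (MCS) performs: one attempt to bind at the TSS
with probability $\alpha\,dt$ if the promoter is on and site 1 is free; one
attempt to unbind at the TTS with probability $\beta\,dt$; then $n-1$
elongation attempts, each picking a uniformly random site and moving its
Pol II forward with probability $\gamma\,dt$ ($\gamma_0\,dt$ for the first
hop) if the next site is free; finally one promoter-switch attempt with
rates $k_{on}, k_{off}$ when bursting is enabled. Exclusion is strict: no
overlap, no bypass. Each loaded Pol II is tagged with the burst episode
(on-period) during which it loaded; a **train** is the set of Pol IIs
sharing a tag, and the train count is the number of distinct tags on the
gene.

Rates are per minute; the default MCS duration is $dt = 5\times10^{-5}$ min
(3 ms), the value obtained from the MSD time calibration below. Per-attempt
probabilities are capped at $\mathrm{rate}\times dt \le 0.1$ to bound
discretization bias; `tasep_params()` rejects configurations beyond the cap.
With the 2-kb monomer, $\gamma = 1$/min is an elongation speed of 2 kb/min,
the biologically typical value, which sits in the slow-elongation regime
where condensation is maximal.

With $\gamma_0 = \gamma$ and $\beta/\gamma = 1 - \alpha/\gamma$ the
steady-state profile is uniform at density $\alpha/\gamma$; this
"uniform-profile family" is used for density sweeps. The continuum
mean-field steady state obeys
$(2n)^{-1}\rho'' + (2\rho - 1)\rho' = 0$ with boundary values taken as
$\rho(0) = \alpha/\gamma$ and $\rho(1) = 1 - \beta/\gamma$ (the natural
reading of the loading/unloading limits; the two coincide in the uniform
family). `solve_meanfield()` integrates this by damped Newton iteration on a
central finite-difference grid (default 400 intervals, residual tolerance
$10^{-10}$) and returns the constant solution exactly when the boundary
values agree. For small $n$, `tasep_exact_stationary()` builds the exact
one-MCS transition matrix over all $2^n$ states — the oracle the stochastic
kernel is tested against.

```{r tasep-demo}
g <- 2000 # 1/min, so gamma*dt = 0.1
p <- tasep_params(50, alpha = 0.215 * g, beta = 0.785 * g, gamma = g)
r <- tasep_run(p, steps = 5e5, burn_in = 2e5, thin = 1000, seed = 1)
round(mean(mean_density(r)$density[10:40]), 3)
```

## The lattice polymer

The chromatin fiber is a self-avoiding chain on the FCC lattice (integer
sites with even coordinate sum; 12 neighbors at permutations of
$(\pm1,\pm1,0)$), with periodic boundaries and a box sized so the chain
occupies 50% of lattice sites — the density that matches a 2-kb/50-nm
monomer to typical mammalian nuclear DNA density. The Hamiltonian is

$$H = \kappa \sum_i (1 - \cos\theta_i) + E \sum_{(i,j)} f_{ij} s_i s_j,$$

with bending rigidity $\kappa = 1.2\,kT$ (a 100-nm Kuhn length) and
$f_{ij} = 1$ when monomers $i,j$ occupy nearest-neighbor sites. The second
sum runs over the **interaction lists**: with finite valency $v$, each
Pol II-bound monomer may hold at most $v$ simultaneous partners. Lists are
re-resolved after every accepted polymer move and every TASEP occupancy
change: pairs persist while both partners remain bound and adjacent
(no spontaneous reshuffling), and freed slots are refilled by scanning
adjacent bound monomers in random order. Chain-consecutive bound monomers
are always adjacent and are eligible pairs — the literal reading of the
Hamiltonian — which contributes to the strong screening of 3D contacts at
high density under small valency. "Unlimited" valency is capped at the FCC
coordination number 12, which no monomer can exceed anyway.

Moves are single-monomer relocations: a uniformly random monomer may move
to a vacant site drawn from the sites adjacent to both its chain neighbors
(either neighbor's full neighbor shell for chain ends), preserving
connectivity and excluded volume by construction; acceptance is Metropolis
on $\Delta H$ ($kT = 1$). The incremental $\Delta H$ is computed against the
hypothetically re-resolved lists and committed or rolled back atomically, so
it is exactly consistent with a from-scratch recomputation (the test suite
audits this to $10^{-9}$). One MCS is one TASEP sweep per gene followed by
$N$ trial moves. TASEP moves are energy-independent — Pol II-Pol II
attraction never blocks elongation, consistent with the high stall force of
Pol II.

**Initial configuration.** A layered serpentine: within each even-$y$ plane
the FCC sites map bijectively onto a rectangle in rotated coordinates, where
a boustrophedon path is a nearest-neighbor walk; consecutive planes are
traversed in opposite order and joined through a single connector site in
the odd plane between them. The result is self-avoiding, unknotted (a stack
of planar serpentines), and fills the box uniformly at 50%. Runs discard a
burn-in before sampling; the gyration radius and energy of the gene relax
well within the burn-ins used in the shipped analyses.

**Positions** are stored unwrapped (wrapping is applied only for collision
and contact detection), so gyration radii and MSDs need no unwrapping pass.
The lattice coordinate unit is $50/\sqrt{2}$ nm (bond length 50 nm).

## Observables

- **Simulated contact maps** count nearest-neighbor (FCC-adjacent) monomer
  pairs per snapshot — the same proximity criterion as $f_{ij}$ — averaged
  over snapshots and replicates.
- **Simulated IC** applies the experimental IC definition to the simulated
  obs/exp map. On a desk-scale region the condensed gene itself would
  contribute a sizable share of the pairs at short separations and deflate
  its own enrichment, so by default the distance-decay expectation is
  estimated from background (non-gene) bins only; on genome-sized maps the
  two estimators agree.
- **RG** is the root-mean-square distance of gene monomers from their
  centroid, in nm.
- **MSD** is time- and ensemble-averaged over log-spaced lags for interior
  gene monomers (central half of the span, avoiding end effects), fit as
  $D\,\Delta t^\delta$ by least squares in log-log space over lags of
  10–1000 snapshots by default. No center-of-mass drift subtraction is
  applied (local lattice moves have no global drift); an interior subdiffusive
  regime with $\delta \approx 0.5$ appears for all Pol II densities.
  Mobility comparisons between conditions are made on the MSD at a fixed lag
  (about 9.3 s, i.e. 3100 MCS) rather than on the fitted prefactor, since
  seed-level wiggles in $\delta$ would otherwise confound the prefactor.
- **Time calibration**: matching the simulated prefactor (in
  $\mu m^2/\mathrm{MCS}^{\delta}$) to the reference live-imaging law
  $0.01\,\mu m^2/s^{0.5}$ gives $\tau = (D/0.01)^{1/\delta}$ seconds per
  MCS $\approx 3$ ms; the calibration refuses fits with
  $|\delta - 0.5| > 0.1$.
- **Burst-conditioned statistics** split RG samples by promoter state and
  rank-correlate instantaneous gene density with RG; at slow bursting the
  on-state ensemble is more compact than the off-state one.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run scaled-down versions of the
full model: chains of 120–1000 monomers at 50% fill (box chosen nearly
cubic; thin boxes would let a collapsed gene touch its periodic images),
genes of 30–128 monomers, $10^5$–$10^7$ MCS with burn-ins of
$2\times10^4$–$6\times10^5$ MCS, and 2–8 replicate trajectories. These
sizes were chosen as the smallest at which the phenomenology is
well-resolved: the theta collapse of a 50–64-monomer gene at
$E = -3\,kT$ completes well within the burn-in, whereas the *swelling* of a
low-occupancy gene from the compact initial state has no energetic drive
and relaxes much more slowly — the low-density arms of density sweeps
therefore get the longest burn-ins and pooled replicates (the gene also
sits near its theta point there and fluctuates between swollen and
partially collapsed states). Bursting analyses use the longest runs
($10^7$ MCS) so that several complete promoter cycles are sampled.
Relative to the full-scale model the background chain is shorter, so
absolute IC values are smaller than genome-scale ones even with the
background-expectation correction; fold-ratios between matched conditions
are the robust quantities and are what the acceptance script reports.

Randomness: the C++ kernels use a self-contained xoshiro256++ generator
seeded from the integer `seed` argument, so multi-billion-draw trajectories
are fast and bit-reproducible across platforms; R-level helpers
(occupancy draws, synthetic data) use R's RNG via `set.seed`. Degenerate
inputs are handled explicitly: genes shorter than two bins have undefined
IC; diagonals with no unmasked pixel propagate as masked; rescaling never
upsamples; `k_off = 0` flags a divergent train size; a gene whose $3l$
window leaves the chromosome is skipped and counted.

## The synthetic generator: what it does and does not emulate

The generator produces matrices whose baseline depends only on separation
($(d+1)^{-\text{exponent}}$ in bins), with multiplicative intra-gene
enrichment $g$, TSS–TTS loop and promoter-stripe factors, and unit-mean
multiplicative lognormal pixel noise symmetrized by averaging the two
triangles (positivity- and symmetry-preserving). Tracks are plateau plus
Gaussian TSS/TTS peaks over a constant background, evaluated on a regular
bedGraph grid, with the TSS at the genomic right edge for reverse-strand
genes. It does **not** simulate read-level ligation noise, matrix-balancing
artifacts, compartment checkerboards, or replication-timing structure:
passing tests demonstrate the estimators recover implanted signal under the
stated noise model, not robustness to every artifact of real Micro-C.

## Interfaces

Plain-text formats throughout: dense text matrices (`write_contact_matrix`),
bedGraph tracks and BED/GTF genes via `rtracklayer` (0-based half-open on
disk, 1-based `GRanges` in memory). `inst/scripts/genefold` provides `synth`
and `score` subcommands for shell use; simulations and pileups are driven
from R, as in this vignette.

## Known limitations

- The move set is local single-monomer relocation; it is ergodic for the
  dilute and semi-dilute systems used here but relaxes dense globules
  slowly, which is why burn-ins are long relative to sampling windows.
- Pol II footprints are one monomer (2 kb); pausing, backtracking and
  supercoiling are not modeled.
- Absolute simulated IC values depend on the background-chain length at
  desk scale (see above); comparisons across conditions at matched scale
  are the meaningful outputs.
- The IR normalization of real ChIP tracks is dataset-dependent; IR-bin
  labels are therefore relative to the input track's own scale.
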