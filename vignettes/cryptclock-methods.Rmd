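---
title: "Models and methods behind cryptclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cryptclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cryptclock` reconstructs the clonal evolution of a Barrett's esophagus (BE)
segment from allele-specific copy-number profiles of single crypts and
whole-biopsy epithelium sampled at known positions (cm from the
gastro-esophageal junction, GEJ) and at one or two time points. The pipeline
is: allele-specific breakpoint markers, maximum-parsimony phylogenies with
diversity statistics, Bayesian estimation of the somatic copy-number
alteration (SCA) rate, segment onset age and effective population size under
strict and random local clocks, genome-doubling calls, and spatial
statistics. Everything downstream of joint segmentation is in scope; raw
SNP-array processing (quality control, GC-wave correction, segmentation,
allele-specific genotyping) is upstream and out of scope. Sex chromosomes
are excluded throughout: allele-specific states are confounded on X/Y.

# Breakpoint markers and allele phasing

A *breakpoint marker* is a (chromosome, boundary position, allele) triple at
which the copy number of one allele changes. Chromosome start and end act as
pseudo-boundaries so that whole-arm and whole-chromosome events — the most
common clonal founder lesions in BE, such as 9p loss or copy-neutral LOH —
are scoreable characters. Marker identity deliberately ignores the
magnitude of the copy-number change: markers are binary presence/absence
characters for parsimony, so a 1→0 step and a 1→0-then-further history at
the same boundary are the same character.

Incoming profiles carry arbitrary per-chromosome allele labels. To decide
whether two samples gained/lost the *same* haplotype (shared ancestry) or
opposite ones (independent events), `phase_alleles()` makes labels
consistent greedily: samples in order of decreasing alteration count, per
chromosome the two possible labelings scored by the *support-weighted*
number of markers shared with already-labelled samples (each shared marker
counts once per labelled sample carrying it). The weighting matters: a
single genotype with breakpoints on both alleles at one boundary would
otherwise tie the vote. Phasing is fundamentally unidentifiable on a
chromosome where groups of samples share no alteration, and the simulator
provides haplotype truth to quantify the residual error; consequences are
limited to splitting or merging marker columns.

# Parsimony trees and distances

Trees are rooted by an explicit all-absent `normal` pseudo-tip: BE descends
from an unaltered ancestor. The Fitch score *always includes this tip*, so
ubiquitous markers cost one change on the ingroup stem. Search is either
exhaustive (≤ 9 samples) or heuristic (random stepwise addition plus
nearest-neighbour-interchange hill climbing, `n_restarts` times);
co-optimal topologies are recorded and ties broken by the lexicographically
smallest canonical Newick string, so results are reproducible given the
seed. Branch lengths are minimum-change counts from a unit-cost Sankoff
backtrack; ties in change placement are resolved ACCTRAN-style (change as
early as possible) by default, switchable to DELTRAN — this redistributes
changes among branches but never alters the total, which always equals the
Fitch score. Evolutionary distance between samples is the patristic
distance on this tree; the mean pairwise distance of a group is its
diversity. The `normal` tip is excluded from diversity statistics.

# The copy-number clock

Each locus × allele evolves independently as a birth-death chain on copy
states 0..K (default K = 4): each existing copy gains at rate ρλ and is
lost at rate (1−ρ)λ, so the total rate out of state c is proportional to c,
matching the rate unit *events per allele copy per locus per year*. State 0
is absorbing — loss of heterozygosity is irreversible. λ is the SCA rate,
ρ the gain fraction. Transition matrices are matrix exponentials (eigen
route with a uniformisation fallback). The likelihood is Felsenstein
pruning over loci × alleles on a time-calibrated tree whose tips sit at the
sampling ages; the unaltered ancestor (root of the model, age `root_age`)
carries state 1 per allele and connects to the sample MRCA by a stem
branch, on which the clonal founder events accrue. `NA` tip states are
marginalised.

Genome doubling is *not* a state-doubling operator inside the chain (which
would square the state space); it is overlaid as an independent
irreversible binary character per sample with its own rate. Samples called
genome-doubled (length-weighted ploidy > 3; the threshold is configurable
because the source literature states both > 3 and ≥ 3) have their
per-allele states halved toward the nearest integer before entering the
chain.

Priors (the source analyses do not state theirs; these are deliberately
weak): λ log-uniform on [1e-5, 1]; ρ uniform; coalescent scale `Ne_tau`
log-uniform on [0.1, 1000] years with a constant-size heterochronous
coalescent tree prior; `root_age` uniform on the 60 years before the
earliest sampling age, truncated below the sample MRCA; GD rate log-uniform
on [1e-5, 1]/year. The random local clock places a Poisson(ln 2) prior on
the number of branch rate changes (prior probability of at least one change
= 1/2), uniform over placements, with log-normal(0, 1) multipliers; the
effective rate of a branch is λ times the product of active multipliers on
its root path. With all indicators off the RLC likelihood is *identical*
to the strict clock — an exact invariant under test.

Sampling is Metropolis-Hastings with scale moves, a reflected random walk
on ρ, uniform node-height slides, narrow exchange for topology, a joint
rate-up/tree-down scaling ("updown", which also scales `Ne_tau`), a
root-age slide (window draw mixed with a local random walk; a slide rather
than the scale move used elsewhere, since the root age is bounded on both
sides), indicator flips with prior-draw multiplier proposals (the Poisson /
placement ratio is the only surviving Hastings term), and an independence
"draw from the prior" move for scalar parameters whose acceptance is the
bare likelihood ratio — with no data this yields near-iid prior samples,
which is what makes prior-recovery testing by Kolmogorov–Smirnov sound.
Chains start from an average-linkage (UPGMA-like) tree on Manhattan
distances of the copy states: a prior-drawn starting tree frequently
strands short chains in a deep-tree, low-rate mode; the starting point
affects only convergence, never the target.

Crypt-level and biopsy-level data are run as separate chains and compared
with `posterior_overlap()`, the overlapping coefficient
∫ min(f_A, f_B) of Gaussian kernel density estimates on a shared grid —
the source describes a "probability of the two posteriors being the same"
without a formula; the OVL is our choice and is labelled as such.

# The synthetic cohort generator

The generator states a desk-scale world mirroring the study design: per
patient arm, non-progressors contribute 3 endoscopic biopsies at each of
two time points a mean of 79 months apart, progressors 3 endoscopic
biopsies plus 8 surgical biopsies 30 months later; every biopsy yields 8
crypts (4 baguette sections × 2 adjacent crypts) and one remaining
epithelium sample — 9 samples per biopsy, 612 in the default cohort. The
toy genome is 4 chromosomes × 50 Mb in 2 Mb loci; every locus exceeds the
1 Mb minimum lesion size the crypt-level arrays support.

Choices worth knowing about:

* **Two-level genealogy.** Crypts of a biopsy coalesce locally
  (`Ne_within` = 1 year) and biopsy-ancestor lineages coalesce across the
  segment (`Ne_tau` = 5 years). A single exchangeable coalescent almost
  never makes a biopsy's crypts a clade, so biopsy consensus profiles would
  collapse to the founder state and no biopsy-level statistic would carry
  signal; clonal patches at the millimetre scale are also what the
  crypt-versus-biopsy literature describes. The *inference* prior remains
  the flat constant-size coalescent.
* **Rates.** Default true rates are 0.005 (non-progressors) and 0.013
  (progressors) events/allele copy/locus/year — the crypt-level means
  reported for the two arms. The GEJ gradient multiplies branch rates by
  exp(−β·d) with β = 0.2/cm and biopsy positions uniform on 0–10 cm;
  internal branches take the mean factor of their descendant crypts' biopsies.
* **Founder anchors.** The founder's clonal events (default 4) are placed
  one per chromosome. Besides matching the ubiquitous-lesion observation,
  they anchor allele phasing: without a shared alteration per chromosome,
  label orientation is unidentifiable and exact pipeline closure would be
  unattainable for reasons that have nothing to do with the code under test.
* **Event modes.** `marker` mode (default) draws breakpoint events at
  constant rate λ × 2 alleles × loci per year and keeps full event-level
  truth; with `unique_events = TRUE` no two events share a locus, a
  boundary, or a boundary position on the other allele, making the
  character matrix provably equal to the truth (up to per-chromosome label
  flips) and the parsimony reconstruction exact. `ctmc` mode runs the exact
  per-allele-copy birth-death chain per locus instead (the simulation-based
  calibration of the clock uses a direct Gillespie simulator on fixed
  trees). Note that one single-locus event produces *two* breakpoint
  markers (its left and right boundary), so tree distances count markers,
  not events; closure identities are stated at marker granularity.
* **Biopsy consensus.** The epithelium profile carries the events present
  in at least a fraction `f_consensus` (default 0.5) of its 8 crypts, and
  genome doubling likewise. This models both the dilution of crypt-private
  events in bulk and the converse — biopsies containing information missed
  by sampled crypts.
* **Noise.** Crypt profiles drop each detected departure from the founder
  state with probability `p_fn` (default 0.1) and gain spurious
  single-locus events at rate 0.5/crypt; biopsy profiles are untouched.
  With `p_fn = 1` crypts revert exactly to the founder state.

What a green test does *not* establish: the generator does not emulate raw
array noise (logR/BAF), segmentation error, fragile-site hypermutability,
translocations, or clone mixtures within a crypt; real-data rate estimates
depend on the unavailable details of the original substitution model and
may differ from the printed ranges even when every property here passes.

# Numerical and testing notes

* Likelihood correctness is pinned to exhaustive ancestral-state
  enumeration (≤ 4 tips, 1e-10) and the transition matrices to
  Chapman–Kolmogorov and a 10^6-path Monte-Carlo chain simulation.
* Prior recovery is tested with exact KS against the stated priors for λ,
  ρ and the GD rate, and two-sample KS against an independent rejection
  sampler for the tree-coupled parameters (`Ne_tau`, `root_age`, MRCA age).
* Rate recovery draws the nuisance truth (tree, ρ, `Ne_tau`, onset) from
  the model prior per replicate with λ fixed at 0.01 — the design under
  which 95% HPD coverage is the calibrated expectation.
* Chain lengths in tests are scaled down (25k steps) relative to the
  production default (2e6); ESS and acceptance rates are reported per run.
* HPD intervals are shortest-interval; ESS uses Geyer's initial positive
  sequence estimator.
* Ties: co-optimal parsimony trees resolve to the smallest canonical
  Newick; window-distance majority states resolve to the lower copy state;
  the Sankoff backtrack resolves toward early (ACCTRAN) or late (DELTRAN)
  changes as configured.

# Known limitations

Phasing is heuristic and unidentifiable without shared alterations;
parsimony ignores the reversibility of gains (binary presence/absence
characters); the clock treats loci as independent and exchangeable with a
shared grid across samples; GD is a single irreversible overlay character;
the spatial statistics take baguette-section separation (0–3 in section
units) as the only within-biopsy physical distance, since no finer
coordinates exist.
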