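---
title: "Models and methods behind pterochron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pterochron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`pterochron` implements the computational stages of a pteropod phylogenomic
dating workflow: cleaning multiplexed transcript expression tables of
index-hopping cross-contamination, assembling an amino-acid supermatrix from
single-copy orthologs, estimating divergence times on a fixed topology under
relaxed molecular clocks with soft-bounded fossil calibrations, and charting
fossil species diversity through time. A synthetic-data generator emulates
every input, so each stage can be exercised and validated end to end without
any external download. This vignette explains the models, the default
parameter values and why they were chosen, the numerical decisions, and what
the validation on synthetic data does and does not establish.

## Contamination filtering

Libraries multiplexed on one sequencing lane can exchange reads through
index misassignment ("index hopping"); the assembler then reconstructs the
leaked molecules as spurious low-abundance transcripts in the wrong dataset.
The filter works on relative expression: for each transcript of a focal
dataset it computes the **contaminant enrichment ratio**, the TPM of the
same transcript in a lane-mate dataset divided by its TPM in the focal
dataset. When several datasets share the lane, the maximum ratio over
lane-mates is used — the conservative choice, since a transcript need only
look contaminant-derived relative to one plausible source; the aggregation
is a parameter, not a hard-wired rule. Two exclusion criteria are applied
independently: enrichment ratio above a fold threshold (default 2), and
estimated count in the focal dataset strictly below a minimum (default 2;
estimated counts are fractional, so the comparison is on real numbers). The
two criteria are reported separately — a transcript failing both is
attributed to the enrichment criterion — so each dataset's transcripts
partition into kept / excluded-by-enrichment / excluded-by-count, and the
per-criterion exclusion fractions can be summarized by medians across
datasets. We read the published description of the rule, which is ambiguous
between requiring one criterion or both, as a union exclusion, because two
separately reported exclusion medians imply separate bookkeeping.

The synthetic expression generator draws true transcript abundances from a
log-normal (meanlog 1, sdlog 1.5 — heavy-tailed, as real expression data
are), forms multinomial read counts, and leaks a binomially thinned fraction
*c* (default 0.05) of each transcript's reads into every lane-mate as a
distinct transcript row tagged with its true origin. Recall and precision of
the filter are therefore measurable exactly. What this does **not** emulate:
sequence-level similarity between sister species' transcriptomes, which in
real data creates legitimately shared transcripts and makes the filter's
precision look better on synthetic tables than it may be in practice.

## Supermatrix construction

Ortholog occupancy filtering keeps genes with at least one of the outgroup
taxa and at least half of the ingroup roster (the threshold count is the
ceiling, so "half" of an odd roster rounds up); both thresholds are
parameters and the roster is supplied by the caller. Column trimming
proceeds in two passes: drop columns whose non-gap fraction falls below 0.15,
then drop columns whose conservation — the frequency of the modal residue
among non-gap residues — falls below 0.001. The original trimming tool's
similarity statistic is not specified in enough detail to clone, so the
modal-residue frequency is used as a simple, monotone conservation proxy
with the published threshold values as defaults. Note the quirk that a 0.15
non-gap threshold corresponds to "gap in more than 85% of taxa", although
the source describes the same flag as 75%; the flag value is taken as
authoritative. Concatenation pads taxa missing from a gene with gaps and
records 0-based half-open column partitions; the missing-data fraction
counts both pads and within-alignment gaps, the convention under which a
published matrix of 834,394 positions carries 35.75% missing data.

Gene informativeness is scored by neighbor-joining bootstrap support rather
than maximum-likelihood tree search: pairwise distances corrected under the
20-state equal-rates model (`d = -(19/20) log(1 - 20p/19)`), an NJ tree,
100 column-bootstrap replicates, and the gene's score is the mean bootstrap
percentage across the internal edges of its tree. This preserves the
selection *procedure* — rank genes by mean support, take the top *k*
(default 200) with ties broken by taxon count then gene id, so the ranking
is deterministic and order-independent — while staying tractable on a
desktop. NJ support and ML rapid-bootstrap support rank genes similarly but
not identically; selections made with this proxy should be treated as
equivalent in spirit, not in gene-by-gene detail.

## The dating model

Divergence times are estimated on a fixed rooted binary topology with all
tips extant. The model has three blocks.

**Node-age prior.** The root age carries a gamma prior parameterized by
mean and SD (defaults 150 and 70 Ma; shape = mean²/SD² ≈ 4.59, rate =
mean/SD² ≈ 0.0306). Non-root internal ages are specified *sequentially*,
root to tips: each node's age, conditional on its parent's age, follows a
kernel truncated to the admissible interval. Three kernels are available:
uniform; the birth–death conditioned reconstructed-process kernel
`V'(t) ∝ ρ(λ-μ)² e^{-(λ-μ)t} / (ρλ + (λ(1-ρ)-μ)e^{-(λ-μ)t})²` with
speciation λ, extinction μ and sampling fraction ρ; and a Dirichlet variant
(uniform kernel with a symmetric Dirichlet tilt of concentration α on
sorted internode-gap proportions; α = 1 coincides with the uniform prior).
Under the birth–death kernel λ and μ carry exponential hyperpriors of mean
0.01 per Myr and are sampled; ρ is fixed at 1 by default. A qualitative
property worth knowing: for μ = 0 the kernel is `e^{-λt}`, so larger
speciation rates concentrate node ages toward the *present* — the
conditioning on a small extant sample forces the splits late.

**Fossil calibrations as soft bounds.** A calibration attaches a fossil
minimum age *m* to the crown (MRCA) node of a named taxon set. Its density
is two-piece: above *m*, the node's kernel reshaped to carry mass
1 − `soft_mass` (default 0.95); below *m*, an exponential ramp carrying
exactly `soft_mass` (default 0.05), continuous at the bound. The sequential
construction is what makes the soft-bound contract *exact*: each node's
support is bounded below by the largest fossil minimum among its calibrated
descendants, so a calibrated node's parent is almost surely older than the
node's own minimum and the conditional probability of violating the bound
is `soft_mass` for every calibration, jointly, regardless of nesting. A
naive multiplicative soft-bound factor on a flat order-constrained prior
does not have this property — truncation interactions between nested
calibrations shift the realized bound-violation masses away from their
nominal value — which is why the sequential form was chosen. The cost is
that the uncalibrated-age prior is the conditional-uniform ("uniform
branching") prior rather than the flat order-constrained prior; on three
taxa the two coincide, and prior-only MCMC is verified against the
closed form there. In the rare degenerate geometry where a continuous ramp
cannot carry the required mass (plateau much wider than the sub-bound
interval), the ramp degrades to a uniform slab with the same mass and a
density step at the bound.

The nine pteropod calibrations (Diacria 7.2, Cavolinia+Diacavolinia+Diacria
28.1, Cavolinia+Diacavolinia 16, Cavolinioidea 47.8, Limacina 47.8, oldest
pteropod 72.1, Pseudothecosomata 16, Gymnosomata 23, and the aplysiidan
outgroup at 133 or 163.1 Ma) are built in, with six schemes (s1–s6)
crossing the outgroup calibration (163.1 / 133 / omitted) with the
placement of the oldest-pteropod fossil (crown Euthecosomata vs crown
Limacinoidea). Schemes s1–s4 yield nine calibrations, s5–s6 eight.

**Relaxed clocks.** Three rate processes, all with stationary mean rate
μ_r in substitutions/site/Myr (default 0.005, which puts roughly 0.75
expected substitutions per site root-to-tip on a 150-Ma tree — typical for
a conserved-ortholog amino-acid matrix):

* *UGAM* — independent gamma branch rates, shape 1/ν (multiplier variance
  ν, default 0.3).
* *Autocorrelated lognormal* — Brownian motion on node log-rates with drift
  −σ²Δt/2 (so the arithmetic mean is stationary), started at μ_r at the
  root; branch rate is the mean of its endpoint node rates (the standard
  node-rate convention). Default σ² = 0.005 per Myr.
* *CIR* — mean-reverting square-root diffusion with reversion θ (default
  0.05 per Myr, a ~20-Myr autocorrelation time) and diffusion σ²; the
  stationary law is gamma with variance σ²μ_r/(2θ), and transitions use
  the exact noncentral-chi-square density. Positivity requires
  2θμ_r ≥ σ²; default σ² = 1e-4 gives a stationary rate CV of about 0.45.

In the sampler, the CIR diffusion is parameterized by
z = σ²/(2θμ_r) ∈ (0,1) — the stationary squared coefficient of variation —
with a flat prior. This keeps the positivity constraint satisfied by
construction and decouples the diffusion from the mean rate, whose own
hyperprior is a diffuse lognormal (median 0.005, log-SD 2). The UGAM ν and
lognormal σ² carry exponential hyperpriors (means 1 and 0.01).

**Likelihood.** Felsenstein pruning over unique site patterns with a
discrete-gamma site-rate mixture (4 categories by default, shape sampled
or fixed at 0.8), under either the 20-state equal-exchangeability
("Poisson") model or LG with its empirical frequencies. Branch expected
substitutions are branch rate × branch duration. The engine (C++, cached
per-edge contribution matrices) recomputes only the path from a changed
edge to the root, which is what makes desk-scale MCMC affordable; it is
validated against exhaustive state enumeration and against two-taxon
closed forms, and its incremental path against full recomputation. The
site-heterogeneous infinite-mixture model used in the original full-scale
analyses is intentionally out of scope; LG/Poisson+Γ is a site-homogeneous
approximation, which is the main reason full-data divergence-time targets
are treated as approximate stretch checks rather than exact ones.

**Sampler.** Metropolis-within-Gibbs: reflected sliding windows for
non-root node ages inside their (children, parent) bracket, a multiplier
for the root, random subtree-scale moves (scale every age inside a random
subtree — important for decorrelating nested clades), a whole-tree age
scale move, per-branch or per-node rate multipliers, a rate–time trade-off
move (ages × c, rates and μ_r ÷ c; likelihood-invariant, it mixes the
direction that calibrations and the root prior alone constrain), and
hyperparameter multipliers. Step sizes adapt toward ~30% acceptance during
burn-in only and freeze afterwards, preserving detailed balance for the
retained samples. Initial states are drawn directly from the sequential
calibrated prior, which doubles as an independent oracle for prior-only
MCMC. Chains are deterministic given the seed.

**Summaries and model choice.** Posterior summaries report per-node means,
2.5–97.5% credibility intervals and an autocorrelation-based effective
sample size (root ESS below 50 raises a convergence warning); the
posterior-mean chronogram is emitted as Newick with durations in Myr.
Cross-validation partitions genes into seeded folds and scores each
clock/prior configuration by the held-out fold log-likelihood at the
plug-in posterior-mean branch lengths — a deterministic, inexpensive proxy
for full posterior-predictive scoring, adequate for ranking configurations.

## Fossil diversity through time

Occurrence records (species, clade, stage, status) are binned on a bundled
stage-level timescale (Jurassic stages through a pooled Pleistocene bin
plus a Recent bin; bounds consistent with the international chart, and
user-replaceable by CSV). Only accepted species count; synonym and doubtful
records are ignored by construction. Records spanning stages
("Chattian–Burdigalian") are expanded to one record per spanned stage.
Observed diversity counts distinct species per stage; range-through
diversity counts each species in every stage between its first and last
occurrence and therefore dominates the observed curve stage-wise. Interval
summaries (median/total/mean over a named stage set, with the even-count
median as the midpoint average) reproduce the kind of figures quoted in
the text, e.g. a Neogene-stage median. The fossil-record simulator gives
each species a contiguous stage range and records it per stage with a
per-stage preservation probability (Recent species always recorded), which
emulates taphonomic bias in intensity but not its time structure —
lithology-driven preservation troughs are representable only by supplying
a per-stage preservation vector.

## Problem sizes used in validation

The validation suite runs at desk scale, chosen so the whole suite
completes in minutes on a single core: prior-only contracts use a 28-taxon
topology with 10⁵ retained sweeps; the node-age recovery study uses three
replicates of 5 genes × 200 amino acids (single rate category) with ~5,000
sweeps each, pooling 81 node-age coverage indicators; the cross-validation
demonstration uses 4–8 short genes and 3–4 folds. These sizes recover the
documented contracts (soft-bound mass within ±0.01, root prior mean/SD
within Monte-Carlo error, ≥90% pooled CrI coverage); larger matrices
tighten posteriors and improve coverage margins but do not change any
qualitative behaviour. The known costs of the desk scale are slower MCMC
mixing per retained sample (root-age ESS of a few tens per short chain)
and wider intervals than a 200-gene analysis would give.

## Known limitations

* Site-homogeneous models only (Poisson/LG + Γ); no CAT-style mixtures.
* Fixed topology; no co-estimation of topology and times, no tip dating.
* The uncalibrated age prior is the sequential conditional-uniform, not
  the flat order-constrained prior; they differ on trees with more than
  one free internal age (a deliberate trade for exact soft-bound masses).
* The Dirichlet age prior with concentration ≠ 1 breaks the exactness of
  the soft-bound contract (it adds a global tilt across nodes) and has no
  direct generative sampler; it is provided for sensitivity analyses.
* Cross-validation uses plug-in held-out likelihood, not posterior
  predictive mass.
* No per-node rate scaling in the pruning engine: numerically safe to a
  few hundred taxa of amino-acid data, not for thousands.
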