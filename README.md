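# pterochron

Divergence-time workflows for pteropod phylogenomics, as a tested R
package. Pteropods (sea butterflies and sea angels) are holoplanktonic
gastropods whose aragonitic shells make them both sentinels of ocean
acidification and a notoriously patchy fossil record; dating their major
divergences requires combining transcriptome-scale ortholog matrices with
fossil minimum-age calibrations. `pterochron` implements the computational
stages of such a study:

* **Contamination filtering** of multiplexed transcript expression tables.
  For a transcript of dataset *d* with lane-mates *m*, the contaminant
  enrichment ratio is `max_m TPM_m / TPM_d`; transcripts with ratio > 2 or
  with estimated count < 2 in the original dataset are excluded, the two
  criteria being reported separately.
* **Supermatrix construction**: single-copy ortholog selection by taxon
  occupancy (≥ 1 outgroup, ≥ half of the ingroup), gap/conservation column
  trimming, concatenation with partition maps and missing-data accounting,
  and gene ranking by mean neighbor-joining bootstrap support.
* **Bayesian relaxed-clock dating** on a fixed topology: Felsenstein
  pruning (Poisson or LG exchangeabilities, discrete-gamma site rates, C++
  core with incremental updates), three rate processes (independent gamma
  multipliers; autocorrelated lognormal; the mean-reverting CIR diffusion),
  three node-age priors (uniform, birth–death with sampled λ and μ,
  Dirichlet), a gamma(mean 150 Ma, SD 70 Ma) root prior, and fossil
  calibrations as *soft* minimum bounds: each calibrated node violates its
  fossil minimum with prior probability exactly 0.05, enforced jointly
  across nested calibrations by a sequential prior construction. The nine
  pteropod calibrations and the six published calibration schemes (s1–s6)
  are built in. Model configurations are compared by k-fold gene-wise
  cross-validation.
* **Fossil diversity through time**: observed and range-through species
  counts per geologic stage from a curated occurrence database, with
  interval summaries (e.g. Neogene-stage medians) and per-clade curves.
* **Synthetic data** for every input: birth–death chronograms, branch
  rates under each clock process, amino-acid alignments with patchy
  occupancy, multi-lane expression tables with injected index-hopping
  contamination (ground-truth labels retained), and stage-binned fossil
  records with preservation bias.

## Worked example

```r
library(pterochron)

tree   <- pteropod_example_tree()                 # known 28-taxon chronogram
calset <- build_calibration_set("s4", tree, pteropod_clade_defs())

# prior-only verification: the soft-bound contract
ch <- run_mcmc(NULL, tree, clock_model("cir"), age_prior("uniform"),
               calset = calset, iterations = 20000, burn_in = 2000, seed = 11)
mean(ch$ages[, paste0("age_", calset$node[calset$label == "f"])] < 72.1)
#> [1] 0.05195     # ~0.05: the oldest-pteropod bound is soft, as designed

# simulate data on the known tree and re-estimate the ages
rates <- sim_branch_rates(tree, clock_model("cir"), seed = 101)
genes <- sim_alignments(tree, rates, n_genes = 5, len_range = c(200, 200),
                        p_missing = 0.15, gamma_shape = Inf,
                        gamma_categories = 1L, seed = 201)
sm  <- concatenate_alignments(genes, tree$phy$tip.label)
fit <- run_mcmc(sm, tree, clock_model("cir"), age_prior("uniform"),
                calset = calset, iterations = 3900, burn_in = 900,
                thinning = 3, seed = 301, gamma_categories = 1L,
                sample_alpha = FALSE)
summ <- summarize_chain(fit, burn_in_fraction = 0)
summ[summ$parameter == "age_29", ]   # the root
#>  parameter     mean    lower    upper      ess
#>     age_29 161.8481 135.4907 214.7462 33.34922
```

The true root age of the example chronogram is 170 Ma and falls inside the
95% credibility interval; across simulation replicates about 95% of true
node ages do (the acceptance suite checks ≥ 90% pooled).

The `analysis/` directory holds the numbered drivers of the full synthetic
study — `01_simulate.R` through `06_fossil_diversity.R` (simulation,
filtering, supermatrix, dating, model comparison by cross-validation,
diversity curves) — each writing its tables under `results/`.

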