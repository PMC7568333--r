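#!/usr/bin/env Rscript
# Cross-validation over relaxed-clock models and node-age priors, the
# procedure used to pick the main analysis configuration.

library(pterochron)

out <- "results/cv"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20240905

tree <- read_newick_dated("results/simdata/true_chronogram.nwk")
calset <- build_calibration_set("s4", tree, pteropod_clade_defs())
top <- utils::head(readLines("results/supermatrix/top_genes.txt"), 8)
genes <- lapply(file.path("results/simdata/genes", paste0(top, ".fasta")),
                read_alignment)
names(genes) <- top

configs <- list(
  cir_bd      = list(clock = clock_model("cir"),
                     prior = age_prior("birth_death")),
  ugam_bd     = list(clock = clock_model("ugam"),
                     prior = age_prior("birth_death")),
  ln_bd       = list(clock = clock_model("lognormal_ac"),
                     prior = age_prior("birth_death")),
  cir_uniform = list(clock = clock_model("cir"),
                     prior = age_prior("uniform")))

cv <- cross_validate(genes, tree, configs, calset = calset, k = 4,
                     iterations = 300, burn_in = 150, seed = seed,
                     gamma_categories = 1L)
print(cv)
utils::write.csv(cv, file.path(out, "cv_scores.csv"), row.names = FALSE)
cat("Best configuration by held-out log-likelihood:", cv$config[1], "\n")
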