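#!/usr/bin/env Rscript
# Stage 1: generate the synthetic museum study that the later stages analyse.
#
# The study mirrors the sampling structure of a large nest collection:
# 55 passerine-like species on an ultrametric phylogeny, 8-25 nests per
# species, three caliper repeats per nest, four correlated log-scale nest
# dimensions, species covariates (body mass, nest type, innovation, clutch
# sizes, builder), and a posterior-like set of phylogenies. We use 200
# jittered trees here to keep the scripted walk-through quick; the package
# default (1000) is what the acceptance run uses.

library(nestvar)

out_dir <- "results/synthetic_study"

cfg <- simulation_config(n_trees = 200, seed = 20260929)
study <- simulate_study(cfg)
write_study(study, out_dir)

n_nests <- tapply(study$specimens$specimen_id, study$specimens$species,
                  function(x) length(unique(x)))
cat(sprintf("Simulated %d species, %d nests total (%.1f +/- %.1f per species),\n",
            length(n_nests), sum(n_nests), mean(n_nests), sd(n_nests)))
cat(sprintf("%d measurement rows, %d trees; written to %s/\n",
            nrow(study$specimens), length(study$trees), out_dir))
cat(sprintf("True generating signal: lambda_means = %g, lambda_cv = %g\n",
            cfg$lambda_means, cfg$lambda_cv))
cat(sprintf("True covariate effects on CV: clutch %g, builder %g, nest type %g, innovation %g\n",
            cfg$clutch_effect, cfg$builder_effect, cfg$nesttype_effect,
            cfg$innovation_effect))
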