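#!/usr/bin/env Rscript
# Stage 5: score the whole pipeline against the generating truth.
#
# Because stage 1 wrote the generator's truth alongside the data, we can ask
# how well the estimated phylogenetic signals and PGLS effects recover the
# values that actually produced the data. This is the calibration evidence
# behind trusting the same pipeline on real specimen tables.

library(nestvar)

study_dir <- "results/synthetic_study"
specimens <- read_specimens(file.path(study_dir, "specimens.csv"))
covariates <- read.csv(file.path(study_dir, "covariates.csv"))
mcc <- parse_newick(readLines(file.path(study_dir, "mcc.nwk"))[1])
trees <- read_tree_set(file.path(study_dir, "trees.nwk"))
truth <- jsonlite::read_json(file.path(study_dir, "truth.json"),
                             simplifyVector = TRUE)

bundle <- suppressWarnings(suppressMessages(
  run_analysis(specimens, covariates, mcc, trees)))
write_report_bundle(bundle, "results/report_bundle")

rec <- compare_to_truth(bundle, truth)
write.csv(rec, "results/recovery.csv", row.names = FALSE)

cat("Recovery of generating parameters (true vs estimated):\n")
print(transform(rec, true = signif(true, 3), estimate = signif(estimate, 3),
                abs_error = signif(abs_error, 2)),
      row.names = FALSE)
cat(sprintf("\nMedian |error| for lambda quantities: %.3f\n",
            median(rec$abs_error[grepl("^lambda", rec$quantity)])))
cat(sprintf("Median |error| for beta quantities:   %.4f\n",
            median(rec$abs_error[grepl("^beta", rec$quantity)])))
cat("Full report bundle written to results/report_bundle/\n")
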