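#!/usr/bin/env Rscript
# Step 1 -- simulate the study cohort.
#
# Builds a 138-patient virtual obese cohort matched to the study's covariate
# marginals, assigns initial-therapy vancomycin regimens from the reported
# dosing grammar, and simulates the sparse TDM concentration records
# (84.4% troughs, 1-2 samples per patient, assay range 4-80 mg/L) under the
# published population model. Outputs feed steps 02-04.

suppressPackageStartupMessages(library(vancopk))
dir.create("results", showWarnings = FALSE)
seed <- 20240604L %% 100000L   # fixed analysis seed

cohort <- make_tdm_cohort(n = 138, pop = published_params(), seed = seed)
popn <- cohort$population
d <- cohort$dataset

utils::write.csv(popn, "results/cohort.csv", row.names = FALSE)
write_tdm(d, "results/tdm_dataset.csv")

cat("== Simulated cohort ==\n")
cat(sprintf("patients: %d (%.0f%% male)\n", nrow(popn),
            100 * mean(popn$SEX == "male")))
for (v in c("WT", "HT", "BMI", "LBM", "BSA", "SCR", "EGFR")) {
  q <- stats::quantile(popn[[v]], c(0.25, 0.5, 0.75))
  cat(sprintf("  %-4s median %7.2f  IQR %7.2f-%-7.2f\n", v, q[2], q[1], q[3]))
}
obs <- d[d$EVID == 0, ]
cat(sprintf("observations retained: %d (drawn %d; %d below / %d above assay range)\n",
            nrow(obs), nrow(obs) + attr(d, "n_bloq") + attr(d, "n_uloq"),
            attr(d, "n_bloq"), attr(d, "n_uloq")))
print(round(100 * table(obs$TYPE) / nrow(obs), 1))
cat("written: results/cohort.csv, results/tdm_dataset.csv\n")
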