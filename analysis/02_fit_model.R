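#!/usr/bin/env Rscript
# Step 2 -- population PK estimation and covariate model building.
#
# Fits the structural one-compartment model to the simulated TDM records by
# adaptive Gauss-Hermite marginal likelihood, screens covariates on the
# empirical-Bayes estimates (Pearson, p < 0.05), runs forward (dOFV > 3.84)
# / backward (dOFV > 6.64) selection, refits the final covariate model with
# RSEs, and bootstraps it (patient resampling).

suppressPackageStartupMessages(library(vancopk))
dir.create("results", showWarnings = FALSE)

d <- read_tdm("results/tdm_dataset.csv")
cohort <- utils::read.csv("results/cohort.csv")

cat("== Structural model ==\n")
base <- fit_population(d, character())
print(base)

cat("\n== Covariate screening (log-EBE vs covariate, Pearson) ==\n")
scr <- covariate_screen(base, cohort,
                        covariates = c("EGFR", "EGFR_CYS", "LBM", "WT", "BMI",
                                       "BSA", "AGE", "SCR", "UREA"),
                        parameters = c("cl", "vd"))
scr <- scr[order(scr$parameter, scr$p_value), ]
print(scr, digits = 3, row.names = FALSE)
utils::write.csv(scr, "results/covariate_screen.csv", row.names = FALSE)
cands <- unique(scr$covariate[scr$candidate & scr$parameter == "cl" &
                                !is.na(scr$p_value)])
cat("\ncandidates on CL:", paste(cands, collapse = ", "), "\n")

cat("\n== Stepwise selection ==\n")
sel <- stepwise_selection(d, cands, init = base$pop)
cat("selected covariates on CL:", paste(sel$selected, collapse = ", "), "\n")
utils::write.csv(sel$trace, "results/selection_trace.csv", row.names = FALSE)

final <- sel$fit
cat("\n== Final covariate model ==\n")
print(final)
if (all(is.na(final$rse_percent))) {
  cat("note: OFV Hessian not positive definite (a near-flat ridge direction);\n")
  cat("      RSEs unavailable -- the bootstrap below quantifies uncertainty.\n")
}
write_pop_params(final$pop, "results/fit_final.json")
utils::write.csv(final$ebes, "results/ebes.csv", row.names = FALSE)
cat(sprintf("\nindividual estimates, median (IQR):\n"))
for (v in c("vd", "cl", "t_half")) {
  q <- stats::quantile(final$ebes[[v]], c(0.25, 0.5, 0.75))
  cat(sprintf("  %-6s %6.2f (%.2f-%.2f)\n", v, q[2], q[1], q[3]))
}

cat("\n== Bootstrap (patient resampling, fixed final structure) ==\n")
boot <- bootstrap_population(d, final$covariates, n_replicates = 40,
                             seed = 77L, init = final$pop)
print(boot)
utils::write.csv(boot$summary, "results/bootstrap.csv", row.names = FALSE)
cat("written: results/fit_final.json, covariate_screen.csv,",
    "selection_trace.csv, ebes.csv, bootstrap.csv\n")
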