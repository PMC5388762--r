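## Initial-condition ensembles for the calibration study.
##
## Draws 100 Latin-hypercube initial-condition sets over the packaged
## per-metabolite concentration bounds (compartment duplicates shared), and
## a 1000-draw Gaussian Monte Carlo ensemble around validated IC #1
## (sd = mean/6, truncated at +/-50%) used later for robustness analysis.

suppressMessages(library(pdacmet))
dir.create("results", showWarnings = FALSE)
seed <- 1

bounds <- ic_bounds()
lhs <- lhs_initial_conditions(bounds, 100, seed = seed)
write_ensemble(lhs, "results/lhs_initial_conditions.csv",
               meta = list(stage = "sample", kind = "latin-hypercube"))

baseline <- with(validated_ic(), setNames(ic1, metabolite))
mc <- gaussian_initial_conditions(baseline, 1000, seed = seed)
write_ensemble(mc, "results/gaussian_initial_conditions.csv",
               meta = list(stage = "sample", kind = "gaussian-mc",
                           baseline = "validated IC #1"))

cat("LHS ensemble: ", nrow(lhs), " sets x ", ncol(lhs), " metabolites\n",
    "Gaussian ensemble: ", nrow(mc), " sets (all within +/-50% of IC #1: ",
    all(mc >= 0.5 * rep(baseline, each = nrow(mc)) &
        mc <= 1.5 * rep(baseline, each = nrow(mc))), ")\n", sep = "")
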