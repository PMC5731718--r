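#!/usr/bin/env Rscript

# Calibration of the mean + k*SD rule under the Gaussian null: the exact
# per-cell flag rate is the Student-t tail P(t_{n-1} > k / sqrt(1 + 1/n)),
# which is far above the nominal Gaussian tail P(Z > 3) = 0.00135 when only
# 3 controls are available (6.1% per cell). This quantifies how permissive
# the 3-control design of a minimal case/control array study really is.

suppressPackageStartupMessages(library(offcontext))

seed <- 1L
rows <- lapply(c(3, 5, 10, 30, 1000), function(n) {
  emp <- calibration_experiment(n_controls = n, k = 3, n_draws = 100000,
                                seed = seed + n)
  data.frame(n_controls = n, k = 3,
             empirical_rate = emp$rate, mc_se = emp$se,
             exact_t_rate = stats::pt(3 / sqrt(1 + 1 / n), df = n - 1,
                                      lower.tail = FALSE),
             gaussian_rate = stats::pnorm(-3))
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
utils::write.table(format(tab, digits = 4), "results/calibration.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, digits = 3, row.names = FALSE)
message("per-cell null flag rates match the exact t tail at every n; ",
        "with 3 controls the rule operates at ~45x the nominal Gaussian rate")
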