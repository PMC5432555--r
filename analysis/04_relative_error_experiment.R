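#!/usr/bin/env Rscript
# Step 4 - the main experiment: relative error of each reference scheme
# against the infinity-reference gold standard.
#
# 100 repetitions per electrode density (21 and 34 channels): generate an
# infinity-referenced dataset, derive Cz / DLM / AVE / REST re-referenced
# copies (REST with the matched spherical model and with a perturbed one),
# estimate bicoherence, cross-bicoherence and antisymmetric
# cross-bicoherence at (6, 10) Hz, and compute the relative errors.  Raw
# values, box-plot summaries and a figure land in results/experiment.
#
#   Rscript analysis/04_relative_error_experiment.R [reps] [seed]

library(bispecref)

args <- commandArgs(trailingOnly = TRUE)
reps <- if (length(args) >= 1) as.integer(args[1]) else 100L
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L

out <- "results/experiment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- exp_config(
  repetitions = reps, densities = c(21, 34),
  schemes = c("Cz", "DLM", "AVE", "REST_matched", "REST_perturbed"),
  master_seed = seed)

t0 <- Sys.time()
res <- run_experiment(cfg, verbose = TRUE, out_dir = out)
cat(sprintf("experiment: %d rows in %.1f min (%d failed repetitions)\n",
            nrow(res$df), as.numeric(difftime(Sys.time(), t0, units = "mins")),
            res$n_failed))

s <- summary(res)
write.csv(s, file.path(out, "re_summary.csv"), row.names = FALSE)
cat("\nmedian RE (%) by scheme, measure, density:\n")
print(reshape(s[, c("density", "scheme", "measure", "median")],
              direction = "wide", idvar = c("scheme", "density"),
              timevar = "measure"), digits = 3)

# box plots in the style of the study figures (log ordinate)
png(file.path(out, "re_boxplots.png"), width = 1400, height = 500, res = 110)
op <- par(mfrow = c(1, 3), mar = c(7, 4, 2, 1))
for (msr in c("b", "cb", "acb")) {
  d <- res$df[res$df$measure == msr, ]
  d$cell <- interaction(d$scheme, d$density, sep = "@")
  boxplot(100 * re ~ cell, data = d, log = "y", las = 2, notch = TRUE,
          main = paste("measure:", msr), ylab = "relative error (%)",
          xlab = "")
}
par(op)
dev.off()
cat("wrote", file.path(out, "re_boxplots.png"), "\n")
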