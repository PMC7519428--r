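#!/usr/bin/env Rscript
# Regenerates the package's default adaptive-span rule.
#
# The NLMD statistic uses a LOESS trend whose span is a linear function of
# the number of available observations, calibrated so the cohort-mean NLMD
# stays put as data go missing. This script runs that calibration on the
# shipped synthetic cohort (first 20 participants, 3 MCAR replicates per
# level) and prints the coefficients frozen in default_span_rule().
#
# usage: Rscript scripts/calibrate_span.R [--seed <int>]

suppressPackageStartupMessages(library(bwvtools))

args <- commandArgs(trailingOnly = TRUE)
seed <- 20240101
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

cohort <- generate_cohort(synthetic_params(n_participants = 20, seed = seed))
rule <- calibrate_span(cohort, levels = c(0.2, 0.4, 0.6, 0.8),
                       seed = seed, replicates = 3)

cat(sprintf("intercept = %.6f\nslope     = %.8f\nbounds    = [%g, %g]\n",
            rule$intercept, rule$slope, rule$span_min, rule$span_max))
print(attr(rule, "calibration"))
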