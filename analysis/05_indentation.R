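#!/usr/bin/env Rscript
# Stage 5: micro-indentation depth gradient.
#
# Bins total indentation distance in 100 um intervals from the canal lumen
# (test and control groups), runs the one-way ANOVA across bins with
# Bonferroni post hoc comparisons, compares test vs control depths within
# 200 um of the lumen (Welch), and fits the logarithmic depth-distance
# trend per group.
# Outputs: results/indent_summary.csv, results/indent_tests.txt.

library(dentinemap)

rec <- read_indentation("results/data/indentation.csv")
tst <- rec[rec$group == "test", ]
ctl <- rec[rec$group == "control", ]

bins <- rbind(cbind(group = "test", bin_depths(tst)),
              cbind(group = "control", bin_depths(ctl)))
write.csv(bins, "results/indent_summary.csv", row.names = FALSE)
cat("mean depth of indentation by distance bin (um):\n")
print(bins[, c("group", "bin", "mean", "sd", "n")], row.names = FALSE, digits = 4)

av <- anova_bins(tst)
nl <- compare_near_lumen(tst, ctl)
lt_t <- fit_log_trend(tst)
lt_c <- fit_log_trend(ctl)

lines <- c(
  sprintf("ANOVA of depth across bins (test group): F(%d, %d) = %.2f, p = %.3g",
          av$df[1], av$df[2], av$f, av$p),
  sprintf("significant Bonferroni pairs: %d of %d",
          sum(av$pairwise$p_adj < 0.05), nrow(av$pairwise)),
  sprintf("near-lumen (<= 200 um) test - control: %.2f um (95%% CI %.2f, %.2f), p = %.3g",
          nl$difference, nl$ci[1], nl$ci[2], nl$p),
  sprintf("test trend:    depth = %.2f - %.2f ln(d + %g), r2 = %.2f",
          lt_t$a, lt_t$b, lt_t$c, lt_t$r2),
  sprintf("control trend: depth = %.2f - %.2f ln(d + %g), r2 = %.2f",
          lt_c$a, lt_c$b, lt_c$c, lt_c$r2)
)
writeLines(lines, "results/indent_tests.txt")
writeLines(lines)
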