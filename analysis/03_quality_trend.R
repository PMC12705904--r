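#!/usr/bin/env Rscript
# Stage 3: spectral quality versus distance from the canal lumen.
#
# Fits the saturating-exponential trend to QI against distance. Because the
# QI of accepted intra-tubular spectra varies little while masked spectra
# are scored 27 regardless of distance, the fit typically explains little
# variance; the caution flag mirrors that situation and the trend is then
# read qualitatively only.
# Output: results/quality_trend.txt.

library(dentinemap)

feats <- read.csv("results/features.csv")
qt <- quality_trend(feats[, c("distance_um", "qi")])

lines <- c(
  sprintf("spectra: %d, accepted: %d", nrow(feats), sum(feats$accepted)),
  sprintf("QI trend r2 = %.3f%s", qt$r2,
          if (qt$caution) " (caution: weak trend, interpret qualitatively)" else ""),
  if (qt$fit$lambda_identifiable)
    sprintf("decay length of QI trend: %.0f um", qt$fit$lambda)
  else "QI decay length not identifiable"
)
writeLines(lines, "results/quality_trend.txt")
writeLines(lines)
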