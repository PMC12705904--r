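#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic irrigation study.
#
# Seven NaOCl-irrigated teeth are sampled at 18 equidistant 50 um points in
# each of the four quadrants (A buccal, B mesial, C lingual, D distal); one
# saline control is sampled at 6 equidistant 150 um points in the buccal
# quadrant. Indentation transects run along every quadrant at 50 um steps.
# Outputs: per-spectrum text files + manifest, indentation and morphometry
# CSVs under results/data/.

library(dentinemap)

seed <- 20260923L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- default_config(seed = seed, n_test = 7L, n_control = 1L)
sim <- simulate_study(cfg)

man <- write_spectra(sim$spectra, sim$manifest[, setdiff(names(sim$manifest), "file")],
                     dir = out)
write.csv(sim$indentation, file.path(out, "indentation.csv"), row.names = FALSE)
write.csv(sim$morphometry, file.path(out, "morphometry.csv"), row.names = FALSE)

cat(sprintf("wrote %d spectra (%d NaOCl, %d control) to %s\n",
            nrow(man), sum(man$treatment == "naocl"),
            sum(man$treatment == "control"), out))
cat(sprintf("indentation records: %d (test %d, control %d)\n",
            nrow(sim$indentation), sum(sim$indentation$group == "test"),
            sum(sim$indentation$group == "control")))
cat(sprintf("teeth: %s\n", paste(sim$morphometry$tooth_id, collapse = " ")))
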