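#!/usr/bin/env Rscript
# Stage 3: extract the 107-feature radiomics vector for each of the 180
# lesion-measurement instances.  Regenerates the simulated volumes from
# the same base seed as stage 1 (the study is fully deterministic), so no
# intermediate image files are needed.

suppressPackageStartupMessages(library(lungphantom))

cfg <- study_config(base_seed = 101L)
report <- suppressWarnings(run_study(cfg, stages = "radiomics",
                                     verbose = TRUE))

dir.create("results", showWarnings = FALSE)
write.csv(report$features, "results/features.csv", row.names = FALSE)
cat(sprintf("feature matrix: %d instances x %d features (+6 provenance columns)\n",
            nrow(report$features), ncol(report$features) - 6))
stopifnot(nrow(report$features) == nrow(report$manifest),
          !anyNA(report$features))
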