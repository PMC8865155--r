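#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Builds the within-participant factorial design (4 instruction conditions x
# 16 trials, 14 participants), draws per-participant preferred tempi, and
# writes the design/ground-truth configuration plus the trial manifest.
# Raw signals themselves are generated on the fly by the later stages (they
# are cheap to reproduce from the seed); one example trial and one example
# optical segment are exported as CSV to illustrate the interchange formats.

suppressPackageStartupMessages(library(simbias))

seed <- 20260929L
config <- design_config(rng_seed = seed)
truth <- ground_truth()

dir.create("results", showWarnings = FALSE)
write_design_json(config, truth, "results/design.json")
manifest <- enumerate_design(config)
write_trials_csv(manifest, "results/trials.csv")

cat(sprintf("design: %d participants x %d conditions x %d trials (+warm-ups)\n",
            config$n_participants, length(config$conditions),
            config$trials_per_block))
cat(sprintf("manifest rows: %d (%d analyzable)\n",
            nrow(manifest), sum(!manifest$is_warmup)))

# perceived-closeness ratings (collected after the AO, AO+MI and
# intentional-imitation blocks; never for MI)
ios <- generate_ios(truth, config$n_participants, seed = seed)
utils::write.csv(as.data.frame(ios), "results/ios.csv", row.names = FALSE)

# example raw export for one trial, illustrating the t_s,x,y,z format
kin <- generate_study_kinematics(manifest[1:2, ], truth, config, seed = seed)
write_kinematics_csv(kin$recordings[[2]], "results/example_trial.csv")
cat("wrote results/design.json, trials.csv, ios.csv, example_trial.csv\n")
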