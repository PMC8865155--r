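#!/usr/bin/env Rscript
# Stage 5 — calibration batches (reduced replicate counts).
#
# Quick Monte-Carlo checks that the pipeline's estimators behave: recovery
# of injected bias ratios, recovery of injected oxygenation amplitudes,
# and the type-I error of the one-way RM-ANOVA under a simulated null.
# The full-size versions of these calibrations (1000 / 500 / 10,000
# replicates) run in the package's test suite; this stage uses reduced
# counts for a fast overview.

suppressPackageStartupMessages(library(simbias))
set.seed(20260929)

rows <- list()

# imitation-bias recovery, 100 replicate blocks per injected ratio
cfg <- design_config(n_participants = 1)
blk <- enumerate_block(cfg, "AO")
main <- blk[!blk$is_warmup, ]
for (r in c(1.0, 1.12, 1.33)) {
  truth_r <- ground_truth(
    bias_ratio = c("AO" = r, "MI" = r, "AO+MI" = r, "IMIT" = r),
    p_invalid = 0
  )
  est <- replicate(100, {
    recs <- lapply(seq_len(nrow(main)), function(i) {
      generate_execution(main[i, ], truth_r, base_ms = 890)
    })
    imitation_bias(filter_invalid(analyze_kinematics(recs, main))$kept)$bias_percent
  })
  rows[[length(rows) + 1]] <- data.frame(
    check = "bias_recovery", parameter = sprintf("r=%.2f", r),
    target = 100 * r, estimate = mean(est), mc_se = sd(est) / 10
  )
}

# oxygenation recovery, 25 sessions, left AO+MI cell
truth <- ground_truth()
man <- enumerate_design(cfg)
tr <- man[man$participant_id == 1, ]
est_oxy <- replicate(25, {
  rec <- generate_fnirs_session(tr, truth, cfg)
  ct <- condition_oxy(process_fnirs(rec)$trial_means, man,
                      fnirs_channel_map())
  ct$oxy[ct$condition == "AO+MI" & ct$hemisphere == "left"]
})
rows[[length(rows) + 1]] <- data.frame(
  check = "oxy_recovery", parameter = "AO+MI left",
  target = truth$oxy_amplitude["left", "AO+MI"], estimate = mean(est_oxy),
  mc_se = sd(est_oxy) / 5
)

# RM-ANOVA size under the null, 2000 replicates
rej <- mean(replicate(2000, rm_anova(matrix(rnorm(14 * 4), 14, 4))[[1]]$p < 0.05))
rows[[length(rows) + 1]] <- data.frame(
  check = "anova_type1", parameter = "alpha=.05", target = 0.05,
  estimate = rej, mc_se = sqrt(0.05 * 0.95 / 2000)
)

out <- do.call(rbind, rows)
utils::write.csv(out, "results/validation.csv", row.names = FALSE)
print(out, row.names = FALSE)
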