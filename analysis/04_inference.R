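#!/usr/bin/env Rscript
# Stage 4 — inferential statistics.
#
# The four dependent measures and their tests, mirroring the study's
# analysis plan: (1) paired t on mean cycle time (ms) between distractor
# speeds; (2) one-way repeated-measures ANOVA on the imitation-bias ratio
# across instructions with Bonferroni pairwise comparisons; (3) two-factor
# RM-ANOVAs for instruction x compatibility (bias, MI excluded) and
# instruction x hemisphere (oxygenation); (4) one-way RM-ANOVA on the IOS
# closeness ratings with Greenhouse-Geisser correction when Mauchly's test
# rejects sphericity.

suppressPackageStartupMessages(library(simbias))

cycles <- utils::read.csv("results/cycles.csv")
bias <- utils::read.csv("results/bias_participants.csv")
bias_compat <- utils::read.csv("results/bias_by_compatibility.csv")
oxy <- utils::read.csv("results/oxy_table.csv")
ios <- utils::read.csv("results/ios.csv")

wide <- function(df, level, value) {
  agg <- stats::aggregate(df[[value]],
                          list(participant_id = df$participant_id,
                               level = df[[level]]), mean)
  stats::xtabs(x ~ participant_id + level, agg)
}

effects <- list()

# distractor speed effect on cycle time (ms)
Y_ms <- wide(cycles, "speed_label", "mean_cycle_time_ms")
t_speed <- paired_t(Y_ms[, "fast"], Y_ms[, "slow"])
t_speed$effect <- "distractor speed (fast - slow, ms)"
print(t_speed)
effects$speed_t <- t_speed

# instruction effect on the imitation bias (%)
Y_bias <- wide(bias, "condition", "bias_percent")
Y_bias <- Y_bias[, c("AO", "MI", "AO+MI", "IMIT")]
a_bias <- rm_anova(Y_bias)[[1]]
a_bias$effect <- "instruction (bias %)"
print(a_bias)
pw <- bonferroni_pairwise(Y_bias)
print(as.data.frame(pw[, c("level_1", "level_2", "t", "p", "p_adj")]),
      row.names = FALSE)
effects$instruction_bias <- a_bias

# instruction x compatibility on the bias (MI carries no compatibility)
bc <- bias_compat[bias_compat$condition != "MI", ]
a_compat <- rm_anova(bc, dv = "bias_percent", subject = "participant_id",
                     within = c("condition", "compatibility"))
for (e in a_compat) print(e)
effects$instruction_compatibility <- a_compat

# instruction x hemisphere on prefrontal oxygenation
a_oxy <- rm_anova(oxy, dv = "oxy", subject = "participant_id",
                  within = c("condition", "hemisphere"))
for (e in a_oxy) print(e)
effects$instruction_hemisphere <- a_oxy

# perceived closeness (IOS), GG-corrected when sphericity is violated
Y_ios <- wide(ios, "condition", "rating")
a_ios <- rm_anova(Y_ios)[[1]]
a_ios$effect <- "instruction (IOS rating)"
print(a_ios)
effects$ios <- a_ios

ser <- function(x) {
  list(effect = x$effect, statistic = x$statistic, df = x$df, p = x$p,
       effect_sizes = x$effect_sizes, corrected = x$corrected)
}
out <- list(
  speed_t = ser(t_speed),
  instruction_bias = ser(a_bias),
  instruction_bias_pairwise = as.data.frame(pw),
  instruction_compatibility = lapply(a_compat, ser),
  instruction_hemisphere = lapply(a_oxy, ser),
  ios = ser(a_ios)
)
jsonlite::write_json(out, "results/effects.json", auto_unbox = TRUE,
                     digits = 12, pretty = TRUE, dataframe = "rows")
cat("wrote results/effects.json\n")
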