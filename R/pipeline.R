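# Study orchestration: generate -> process -> infer as one reproducible
# run, emitting the output tables of the analysis and a run manifest.

effect_to_list <- function(x, n = NULL) {
  out <- list(
    effect = x$effect,
    statistic = unname(x$statistic),
    stat = x$stat_name,
    df = unname(x$df),
    p = unname(x$p),
    effect_sizes = lapply(x$effect_sizes, unname),
    corrected = x$corrected
  )
  if (!is.null(n)) out$n <- n
  if (!is.null(x$sphericity)) {
    out$sphericity <- lapply(x$sphericity, unname)
  }
  if (!is.null(x$ci)) {
    out$ci <- if (is.matrix(x$ci)) {
      stats::setNames(lapply(seq_len(nrow(x$ci)),
                             function(i) unname(x$ci[i, ])),
                      rownames(x$ci))
    } else {
      unname(x$ci)
    }
  }
  if (isTRUE(x$degenerate)) out$degenerate <- TRUE
  out
}

# subjects x levels matrix from a long tibble, preserving level order.
wide_matrix <- function(df, subject, level, value, levels = NULL) {
  levs <- levels %||% unique(df[[level]])
  subj <- sort(unique(df[[subject]]))
  Y <- matrix(NA_real_, length(subj), length(levs),
              dimnames = list(subj, levs))
  Y[cbind(match(df[[subject]], subj), match(df[[level]], levs))] <- df[[value]]
  Y
}

round_cols <- function(df, digits = 9) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Run the full synthetic study
#'
#' One reproducible pass over the whole analysis path: design enumeration,
#' synthetic kinematics, fNIRS and closeness ratings with the ground-truth
#' effect structure, kinematic cycle-time extraction and the imitation-bias
#' ratio, fNIRS processing to condition-by-hemisphere oxygenation, and the
#' inferential layer. Outputs are written under `out_dir`:
#' `bias.csv` (condition-level imitation bias with 95% CIs),
#' `bias_participants.csv`, `oxy_table.csv` (condition x hemisphere),
#' `ios_summary.csv`, `effects.json` (the full effect table) and
#' `manifest.json` (seed, configuration digest, per-file digests). Numeric
#' columns are rounded to 1e-9 before writing so digests are stable across
#' machines.
#'
#' @param config a [design_config()].
#' @param truth a [ground_truth()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for every stochastic stage.
#' @param constants an [mbll_constants()].
#' @param run_fnirs set `FALSE` to skip the (comparatively slow) optical
#'   stage, e.g. for kinematics-only calibration batches.
#' @return Invisibly, a list with the in-memory results: `manifest_trials`,
#'   `cycles`, `filtered`, `bias`, `oxy_table`, `ios`, `effects`,
#'   `warnings`, and the output `paths`.
#' @export
run_study <- function(config = design_config(), truth = ground_truth(),
                      out_dir = tempfile("simbias_run_"),
                      seed = config$rng_seed,
                      constants = mbll_constants(),
                      run_fnirs = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  manifest <- enumerate_design(config)

  # --- kinematics ---------------------------------------------------------
  kin <- generate_study_kinematics(manifest, truth, config, seed = seed)
  cycles <- analyze_kinematics(kin$recordings, manifest)
  filt <- filter_invalid(cycles)
  if (filt$n_discarded > 0) {
    note(sprintf("%d invalid trial(s) discarded (%.1f%%)",
                 filt$n_discarded, filt$discard_percent))
  }
  bias <- imitation_bias(filt$kept)
  bias_compat <- imitation_bias(filt$kept, by_compatibility = TRUE)

  # per-participant mean cycle time by distractor speed (ms analysis)
  ms_speed <- dplyr::summarise(
    dplyr::group_by(filt$kept, .data$participant_id, .data$speed_label),
    mean_ct_ms = mean(.data$mean_cycle_time_ms), .groups = "drop"
  )
  Y_speed <- wide_matrix(ms_speed, "participant_id", "speed_label",
                         "mean_ct_ms", levels = c("fast", "slow"))
  speed_t <- paired_t(Y_speed[, "fast"], Y_speed[, "slow"])
  speed_t$effect <- "distractor speed (fast - slow, ms)"

  # one-way RM ANOVA on the bias ratio across instruction conditions
  Y_bias <- wide_matrix(bias, "participant_id", "condition", "bias_percent",
                        levels = config$conditions)
  aov_instr <- rm_anova(Y_bias)[[1]]
  aov_instr$effect <- "instruction (bias %)"
  pairwise_bias <- bonferroni_pairwise(Y_bias)

  # two-factor instruction x compatibility (MI carries no compatibility)
  bc <- bias_compat[bias_compat$condition != "MI", , drop = FALSE]
  aov_compat <- rm_anova(as.data.frame(bc), dv = "bias_percent",
                         subject = "participant_id",
                         within = c("condition", "compatibility"))
  names(aov_compat) <- c("instruction", "compatibility",
                         "instruction:compatibility")

  # --- fNIRS --------------------------------------------------------------
  oxy_table <- NULL
  aov_oxy <- NULL
  if (run_fnirs) {
    recs <- generate_study_fnirs(manifest, truth, config, seed = seed,
                                 constants = constants)
    tm_all <- vector("list", config$n_participants)
    for (p in seq_len(config$n_participants)) {
      proc <- process_fnirs(recs[[p]], constants = constants)
      n_rej <- sum(!proc$mask$accept)
      if (n_rej > 0) {
        note(sprintf("participant %d: %d channel-window(s) rejected", p, n_rej))
      }
      tm_all[[p]] <- proc$trial_means
    }
    trial_means <- dplyr::bind_rows(tm_all)
    oxy_table <- condition_oxy(trial_means, manifest, fnirs_channel_map())
    aov_oxy <- rm_anova(as.data.frame(oxy_table), dv = "oxy",
                        subject = "participant_id",
                        within = c("condition", "hemisphere"))
    names(aov_oxy) <- c("instruction", "hemisphere",
                        "instruction:hemisphere")
  }

  # --- perceived closeness ------------------------------------------------
  ios <- generate_ios(truth, config$n_participants, seed = seed)
  Y_ios <- wide_matrix(ios, "participant_id", "condition", "rating",
                       levels = names(truth$ios_latent_mean))
  aov_ios <- rm_anova(Y_ios)[[1]]
  aov_ios$effect <- "instruction (IOS rating)"
  pairwise_ios <- bonferroni_pairwise(Y_ios)

  # --- output tables ------------------------------------------------------
  n_subj <- config$n_participants
  bias_summary <- tibble::tibble(
    condition = colnames(Y_bias),
    bias_percent = colMeans(Y_bias),
    ci_lower = aov_instr$ci[, "lower"],
    ci_upper = aov_instr$ci[, "upper"],
    n_participants = n_subj
  )
  ios_summary <- dplyr::summarise(
    dplyr::group_by(ios, .data$condition),
    mean_rating = mean(.data$rating), sd_rating = stats::sd(.data$rating),
    n = dplyr::n(), .groups = "drop"
  )

  paths <- c(
    bias = file.path(out_dir, "bias.csv"),
    bias_participants = file.path(out_dir, "bias_participants.csv"),
    ios_summary = file.path(out_dir, "ios_summary.csv"),
    effects = file.path(out_dir, "effects.json"),
    design = file.path(out_dir, "design.json")
  )
  if (run_fnirs) paths["oxy_table"] <- file.path(out_dir, "oxy_table.csv")

  utils::write.csv(round_cols(bias_summary), paths["bias"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(round_cols(as.data.frame(bias)),
                   paths["bias_participants"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(round_cols(as.data.frame(ios_summary)),
                   paths["ios_summary"], row.names = FALSE, quote = FALSE)
  if (run_fnirs) {
    utils::write.csv(round_cols(as.data.frame(oxy_table)),
                     paths["oxy_table"], row.names = FALSE, quote = FALSE)
  }
  write_design_json(config, truth, paths["design"])

  effects <- c(
    list(
      speed_t = effect_to_list(speed_t, n = n_subj),
      instruction_bias = effect_to_list(aov_instr, n = n_subj),
      instruction_bias_pairwise = round_cols(as.data.frame(pairwise_bias)),
      instruction_compatibility = lapply(aov_compat, effect_to_list,
                                         n = n_subj),
      ios = effect_to_list(aov_ios, n = n_subj),
      ios_pairwise = round_cols(as.data.frame(pairwise_ios)),
      discard_percent = filt$discard_percent
    ),
    if (run_fnirs) {
      list(instruction_hemisphere = lapply(aov_oxy, effect_to_list,
                                           n = n_subj))
    }
  )
  jsonlite::write_json(effects, paths["effects"], auto_unbox = TRUE,
                       digits = 12, pretty = TRUE, dataframe = "rows")

  digests <- tools::md5sum(unname(paths))
  run_manifest <- list(
    package = "simbias",
    version = as.character(utils::packageVersion("simbias")),
    seed = seed,
    config_digest = unname(tools::md5sum(paths[["design"]])),
    files = as.list(stats::setNames(unname(digests), basename(names(digests)))),
    warnings = warnings,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(run_manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    manifest_trials = manifest, cycles = cycles, filtered = filt,
    bias = bias, bias_summary = bias_summary, oxy_table = oxy_table,
    ios = ios, effects = effects, warnings = warnings,
    out_dir = out_dir, paths = paths
  ))
}

#' Render a human-readable run summary
#'
#' Markdown summary of a completed [run_study()] output directory:
#' per-condition imitation bias with confidence intervals, oxygenation by
#' hemisphere, closeness ratings, and the main effects with any Bonferroni
#' pairwise differences flagged.
#'
#' @param out_dir directory written by [run_study()].
#' @param path optional file to write the markdown to.
#' @return The markdown text, invisibly when `path` is given.
#' @export
report <- function(out_dir, path = NULL) {
  need <- c("bias.csv", "ios_summary.csv", "effects.json")
  for (f in need) {
    abort_if(!file.exists(file.path(out_dir, f)),
             sprintf("missing output file '%s' in %s", f, out_dir))
  }
  bias <- utils::read.csv(file.path(out_dir, "bias.csv"))
  ios <- utils::read.csv(file.path(out_dir, "ios_summary.csv"))
  effects <- jsonlite::read_json(file.path(out_dir, "effects.json"),
                                 simplifyVector = TRUE)
  lines <- c(
    "# Synthetic study summary", "",
    "## Imitation bias (%) by instruction", "",
    "| condition | bias % | 95% CI |", "|---|---|---|",
    sprintf("| %s | %.1f | [%.1f, %.1f] |", bias$condition,
            bias$bias_percent, bias$ci_lower, bias$ci_upper),
    ""
  )
  if (file.exists(file.path(out_dir, "oxy_table.csv"))) {
    oxy <- utils::read.csv(file.path(out_dir, "oxy_table.csv"))
    agg <- stats::aggregate(cbind(oxy, oxy_change) ~ condition + hemisphere,
                            data = oxy, FUN = mean)
    lines <- c(lines,
               "## Prefrontal oxygenation (umol/L) by condition and hemisphere",
               "",
               "| condition | hemisphere | oxy | change vs AO |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %.3f | %.3f |", agg$condition,
                       agg$hemisphere, agg$oxy, agg$oxy_change),
               "")
  }
  lines <- c(lines,
             "## Perceived closeness (IOS, 1-7)", "",
             "| condition | mean | sd |", "|---|---|---|",
             sprintf("| %s | %.2f | %.2f |", ios$condition, ios$mean_rating,
                     ios$sd_rating),
             "", "## Effects", "")
  fmt_eff <- function(e) {
    sprintf("- %s: %s(%s) = %.3f, p = %.4g",
            e$effect, e$stat, paste(signif(unlist(e$df), 4), collapse = ", "),
            e$statistic, e$p)
  }
  lines <- c(lines, fmt_eff(effects$speed_t),
             fmt_eff(effects$instruction_bias))
  if (!is.null(effects$instruction_hemisphere)) {
    lines <- c(lines,
               vapply(effects$instruction_hemisphere, fmt_eff, character(1)))
  }
  lines <- c(lines, fmt_eff(effects$ios))
  pw <- effects$instruction_bias_pairwise
  sig <- pw[pw$p_adj < 0.05, , drop = FALSE]
  if (nrow(sig) > 0) {
    lines <- c(lines, "",
               "Significant Bonferroni pairwise bias differences:",
               sprintf("- %s vs %s: p_adj = %.4g", sig$level_1, sig$level_2,
                       sig$p_adj))
  }
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}
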