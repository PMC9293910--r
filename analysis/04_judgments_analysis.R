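#!/usr/bin/env Rscript
# The core statistical chain on the 23-path set: simulate Likert judgments
# from rarity, correlate rarity and model scores with mean ratings
# (bootstrap CIs), calibrate model scores to the Likert scale, measure
# per-class model-human discrepancies, and test whether excluding the
# most discrepant classes raises the model-human correlation more than
# chance exclusions would.

suppressPackageStartupMessages(library(effcomm))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

scores_df <- read.csv("results/model_scores.csv")  # from 03_model_scores.R
ids <- scores_df$path_id

linking <- linking_params(seed = stage_seed(seed, "judgments"))
judg <- simulate_judgments(ids, scores_df$rarity, linking)
m <- path_means(judg)
mr <- m$mean_rating[match(ids, m$path_id)]

cor_rarity <- pearson_bootstrap(scores_df$rarity, mr, n_boot = 10000,
                                seed = stage_seed(seed, "boot-rarity"))
cat("rarity vs mean rating: "); print(cor_rarity)
cor_model <- pearson_bootstrap(scores_df$score, mr, n_boot = 10000,
                               seed = stage_seed(seed, "boot-model"))
cat("model score vs mean rating: "); print(cor_model)

calib <- calibrate_linear(scores_df$score, mr)
cat(sprintf("calibration: rating ~ %.4f + %.4f * score\n",
            calib$intercept, calib$slope))
disc <- class_discrepancy(calib, scores_df$class)
cat("per-class discrepancy (positive = model saw it as more communicative):\n")
print(disc, digits = 3)

# exclude the two most discrepant classes (by |mean residual|) and test the
# correlation increase against random equal-size exclusions
worst <- disc$class[order(-abs(disc$discrepancy))][1:2]
cat("most discrepant classes:", paste(worst, collapse = ", "), "\n")
excl <- ids[scores_df$class %in% worst]
perm <- correlation_increase_permutation(scores_df$score, mr, ids, excl,
                                         n_perm = 10000,
                                         seed = stage_seed(seed, "perm"))
print(perm)

rec <- recover_linking_slope(judg, scores_df$rarity, n_boot = 2000,
                             seed = stage_seed(seed, "recover"))
cat(sprintf("linking slope recovered: %.3f [%.3f, %.3f] (true %.2f)\n",
            rec$slope, rec$ci_low, rec$ci_high, linking$slope))

write_judgments_csv(judg, "results/judgments.csv")
write_report(list(
  seed = seed,
  correlation_rarity = unclass(cor_rarity),
  correlation_model = unclass(cor_model),
  calibration = list(slope = calib$slope, intercept = calib$intercept),
  class_discrepancy = disc,
  excluded_classes = worst,
  permutation = unclass(perm),
  slope_recovery = rec
), "results/judgment_analysis.json")
cat("wrote results/judgments.csv and results/judgment_analysis.json\n")
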