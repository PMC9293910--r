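#!/usr/bin/env Rscript
# Build the three stimulus sets (23 rarity-gradient paths; 21 repetition
# variants equated for distance traveled; 12 bordered/unbordered pairs) and
# write their specifications and rendered trajectories.

suppressPackageStartupMessages(library(effcomm))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results/stimuli", recursive = TRUE, showWarnings = FALSE)

set1 <- build_study1_set(stage_seed(seed, "stimuli"))
cat("study 1:", nrow(set1$items), "paths;",
    sum(set1$items$class == "A"), "maximally efficient\n")
s2 <- build_study2_set()
lens <- vapply(s2$paths, path_length, numeric(1))
cat("study 2:", nrow(s2$items), "trajectories; total length",
    round(lens[1], 4), "(spread", format(max(lens) - min(lens), digits = 3),
    ")\n")

linking <- linking_params(seed = stage_seed(seed, "judgments"))
judg <- simulate_judgments(set1$items$path_id, set1$items$rarity, linking)
s3 <- build_study3_set(set1, judg, seed = stage_seed(seed, "study3"))
cat("study 3:", length(s3$paths), "base paths,", nrow(s3$items),
    "condition items\n")

for (set in list(set1, s2, s3)) {
  jsonlite::write_json(
    list(study = set$study, seed = set$seed,
         items = cbind(set$items,
                       segments = I(unname(lapply(set$paths[set$items$path_id],
                                                  function(p) p$segments))),
                       scale = vapply(set$paths[set$items$path_id],
                                      function(p) p$scale, numeric(1)))),
    sprintf("results/stimuli/%s.json", set$study),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  trajs <- do.call(rbind, lapply(names(set$paths), function(pid) {
    cbind(path_id = pid, compose_path(set$paths[[pid]])$frames)
  }))
  write.csv(trajs, sprintf("results/stimuli/%s_trajectories.csv", set$study),
            row.names = FALSE, quote = FALSE)
}
write_world(s3$worlds[[1]], "results/stimuli/study3_world_example.json")
cat("wrote stimulus sets and trajectories under results/stimuli/\n")
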