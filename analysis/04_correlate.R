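#!/usr/bin/env Rscript

# Stage 4 — the three correlation analyses.
#
# (i) subject by subject: one r per subject and feature, mean +/- SD
#     summary, and strength bins on PAT_RS*;
# (ii) collective: all beats pooled, against SBP, MAP, and DBP;
# (iii) one excellent beat per subject, selected by per-beat SQI.
# Rendered tables go to results/reports/.

library(patcor)

ft <- read.csv("results/beat_features.csv")
dir.create("results/reports", showWarnings = FALSE, recursive = TRUE)

subj <- analyze_subject_by_subject(ft)
render_reports(subj, "results/reports")
message(sprintf("subject-by-subject (n = %d): mean r(SBP, PAT_RS*) = %.2f",
                nrow(subj$rows),
                subj$summary$mean_r[subj$summary$feature == "pat_rsstar"]))
message("strength bins on PAT_RS*: ",
        paste(names(subj$strength_bins), subj$strength_bins,
              sep = "=", collapse = ", "))

pooled <- NULL
for (bp in c("sbp", "map", "dbp")) {
  coll <- analyze_collective(ft, bp)
  exc <- analyze_one_excellent_beat(ft, bp)
  pooled <- rbind(pooled,
                  cbind(trial = "collective", bp = toupper(bp), coll$rows),
                  cbind(trial = "one_excellent_beat", bp = toupper(bp),
                        exc$rows))
  message(sprintf("collective %s (n = %d): r(PAT_Rb) = %.2f; ",
                  toupper(bp), coll$rows$n_beats, coll$rows$pat_rb),
          sprintf("one-excellent-beat (n = %d): r(PAT_Rb) = %.2f",
                  exc$rows$n_beats, exc$rows$pat_rb))
}
num <- vapply(pooled, is.numeric, logical(1)) & names(pooled) != "n_beats"
pooled[num] <- lapply(pooled[num], round, digits = 2)
write.csv(pooled[names(pooled) != "scope"], "results/reports/pooled_r.csv",
          row.names = FALSE)
message("wrote results/reports/")
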