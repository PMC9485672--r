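#!/usr/bin/env Rscript
# Stage 1 -- simulate the study.
#
# Draws the default simulated study: 11 patient-therapist dyads, one
# 2-minute pretalk and one 2-minute posttalk movement segment each at
# 30 fps, with coupling strengthening after the intervention (alpha
# 0.2 -> 0.5), lead direction flipping from therapist to patient, and a
# ceiling-limited VAS readiness score with one missing response.
# Writes per-segment movement text files (one column per person), the
# session-metadata table, the VAS scores, and a ground-truth sidecar.

library(dyadsync)

seed <- 20
data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

study <- gen_study(study_spec(seed = seed))

for (id in names(study$segments)) {
  sg <- study$segments[[id]]
  for (ph in c("pre", "post")) {
    me <- mea_series(cbind(sg[[ph]]$patient, sg[[ph]]$therapist),
                     fps = 30, labels = c("patient", "therapist"))
    write_mea_text(me, file.path(data_dir, sprintf("%s_%s.txt", id, ph)))
  }
}
write.csv(study$sessions, file.path(data_dir, "sessions_sim.csv"),
          row.names = FALSE)
write.csv(data.frame(dyad_id = study$sessions$dyad_id, vas = study$vas),
          file.path(data_dir, "vas.csv"), row.names = FALSE)
jsonlite::write_json(
  list(seed = seed,
       pre_alpha = study$spec$pre_coupling$alpha,
       post_alpha = study$spec$post_coupling$alpha,
       pre_delta_s = study$spec$pre_coupling$delta_s,
       post_delta_s = study$spec$post_coupling$delta_s,
       n_dyads = study$spec$n_dyads, fps = 30, duration_s = 120),
  file.path(data_dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("Simulated %d dyads (seed %d): %d segment files under %s\n",
            study$spec$n_dyads, seed, 2 * study$spec$n_dyads, data_dir))
cat(sprintf("VAS readiness: %d responses, range %.1f-%.1f%%, 1 missing\n",
            sum(!is.na(study$vas)), min(study$vas, na.rm = TRUE),
            max(study$vas, na.rm = TRUE)))
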