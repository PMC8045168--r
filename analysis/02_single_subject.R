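#!/usr/bin/env Rscript
# Plan both screws for one synthetic acromion end to end and write the
# inspection artifacts: the safe-corridor map (PGM + frame sidecar), the
# screw plans (JSON), and the measurement row (CSV). Also verifies the
# planned direction and downdip angle against the generator's ground truth.

suppressPackageStartupMessages(library(acroplan))

dir.create("results/subject", recursive = TRUE, showWarnings = FALSE)

subject <- generate_acromion(acromion_params(seed = 20240301))
res <- run_subject(subject = subject, subject_id = "demo", sex = "M",
                   config = plan_config(spacing = 0.25))

cat("Planned screws:\n")
print(res$screws$medial)
print(res$screws$lateral)
cat("\nMeasurement row:\n")
print(as.data.frame(res$measurement), digits = 3, row.names = FALSE)

ang <- acos(min(1, abs(sum(res$direction * subject$truth$chord_dir)))) *
  180 / pi
cat(sprintf("\nPlanned corridor direction is %.2f deg from the generator's
centerline chord; measured downdip %.1f deg vs ground truth %.1f deg.\n",
            ang, res$measurement$alpha, subject$truth$alpha_deg))

write_safe_map(res$map, "results/subject/safe_map")
write_screw_plans(res$screws, "results/subject/screws.json")
write.csv(res$measurement, "results/subject/measurement.csv",
          row.names = FALSE)
save_mesh(subject$mesh, "results/subject/acromion.stl")
write_landmarks(subject$landmarks, "results/subject/landmarks.json")
cat("wrote results/subject/{safe_map.pgm,screws.json,measurement.csv,",
    "acromion.stl,landmarks.json}\n", sep = "")
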