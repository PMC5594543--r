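#!/usr/bin/env Rscript

# Stage 2 — Crt-panel quality control and normalization.
#
# Applies the unamplified-well rule (Crt > 28, AmpScore < 1.1, or missing
# -> Crt 29), drops assays amplified in no subject, scores candidate
# normalization strategies with geNorm and NormFinder, and writes the
# normalized log2 expression matrices: global-mean normalization for the
# discovery (screening) panel, endogenous + exogenous control pair for the
# validation panel (a subject-wise global mean is not meaningful on a
# 40-assay custom panel).
#
# Writes results/preprocess/{stage}_expression.csv, qc_report_{stage}.json,
# and stability_discovery.csv.

suppressPackageStartupMessages(library(evmir))

out_dir <- "results/preprocess"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (stage in c("discovery", "validation")) {
  root <- file.path("results/data", stage)
  panel <- read_crt_panel(file.path(root, "crt.csv"),
                          file.path(root, "ampscore.csv"))
  qc <- apply_qc(panel, qc_config())
  dropped <- drop_never_amplified(qc)
  kept <- dropped$panel
  cat(sprintf("%s: %d wells unamplified, %d assays dropped, %d retained\n",
              stage, sum(!qc$expressed), length(dropped$dropped),
              length(setdiff(kept$assay_ids, kept$control_ids))))

  if (stage == "discovery") {
    stab <- stability_report(kept)
    print(stab, row.names = FALSE)
    utils::write.csv(stab, file.path(out_dir, "stability_discovery.csv"),
                     row.names = FALSE)
    strategy <- normalizer_global_mean()
  } else {
    strategy <- normalizer_control_pair(endogenous = "U6",
                                        exogenous = "ath-miR159a")
  }
  expr <- normalize_expression(kept, strategy)
  cat(sprintf("  normalization: %s (%d subject-level failures)\n",
              expr$strategy$label, length(expr$failed_subjects)))
  qc_report(panel, qc, dropped$dropped, expr,
            path = file.path(out_dir, sprintf("qc_report_%s.json", stage)))

  df <- data.frame(subject_id = rownames(expr$log2_values),
                   expr$log2_values, check.names = FALSE)
  utils::write.csv(df,
                   file.path(out_dir, sprintf("%s_expression_log2.csv", stage)),
                   row.names = FALSE)
}
cat("wrote", out_dir, "\n")
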