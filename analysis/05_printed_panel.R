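#!/usr/bin/env Rscript
# Stage 5: the published-table path.
#
# Applies the identical panel set algebra directly to the packaged
# transcription of the published per-miRNA status table (direction in the
# uterine-aspirate contrast; up/down/ns status in the ascitic-fluid and
# ascites-cell columns), bypassing the engines. This reproduces the
# published tier counts by pure set logic.

suppressMessages(library(evmirpanel))

out <- run_pipeline("results/printed", fixture_only = TRUE)
print(out$panel_report)
cat("Three-fluid members:",
    paste(out$panel_report$panel$mirna_id[
      out$panel_report$panel$tier == "three_fluid"], collapse = ", "), "\n")
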