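#!/usr/bin/env Rscript
# Stage 3: unanimous three-engine consensus calls and the two reference
# tiers.
#
# A miRNA is called only when all three engines independently satisfy
# FDR < 0.01, FC > 2 and logCPM > 2 with agreeing signs (base tier,
# "set 1"); the strict tier ("set 2") additionally requires FDR < 0.001
# everywhere. Also reports how much larger each engine's own call set is
# than the unanimous consensus.

suppressMessages(library(evmirpanel))

contrasts <- c("UA-OC:UA-N", "AF:UA-N", "AF:UA-OC", "AC:UA-N", "AC:UA-OC")
engines <- c("nb_lrt", "voom_lm", "nb_wald")

for (ct in contrasts) {
  stub <- gsub(":", "_vs_", ct)
  res <- lapply(setNames(engines, engines), function(e)
    utils::read.delim(file.path("results/de", paste0(stub, "_", e, ".tsv"))))
  cons <- run_consensus(res)
  write_results_tsv(cons, file.path("results", paste0("consensus_", stub, ".tsv")))
  cat(ct, ":", sum(cons$direction != "ns"), "base-tier calls (",
      sum(cons$tier == "set2"), "strict-tier )\n")
  if (ct == "UA-OC:UA-N") {
    write_results_tsv(de_set(cons, "set1", ct), "results/set1.tsv")
    write_results_tsv(de_set(cons, "set2", ct), "results/set2.tsv")
    tab <- engine_vs_consensus_counts(cons)
    write_results_tsv(tab, "results/engine_vs_consensus.tsv")
    cat("  single-engine vs consensus:",
        paste(tab$caller, tab$n_significant, collapse = ", "), "\n")
  }
}
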