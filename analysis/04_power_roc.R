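#!/usr/bin/env Rscript
# Architecture-dependent power. Two presets with 50 causal + 200 null
# genes, 20 replicates, n = 697, paired permutation streams:
#   rare_only        every causal variant has MAF < 5% -> the fixed 5%
#                    threshold (T5) captures all signal and beats VT,
#                    which pays for searching thresholds above 5%
#   rare_plus_common each causal gene has one rare and one MAF ~ 0.17
#                    causal variant -> T1/T5 discard the common signal
#                    and VT recovers it
#
# Writes: results/power_summary.tsv, results/roc_points.tsv

suppressPackageStartupMessages(library(rarepool))
dir.create("results", showWarnings = FALSE)
seed <- 20260922L %% 1000000L

blocks <- list(rare_only = list(preset = "q1like", trait = "Q1"),
               rare_plus_common = list(preset = "q2like", trait = "Q2"))
summ <- list(); rocs <- list()
for (tag in names(blocks)) {
  b <- blocks[[tag]]
  ds <- simulate_dataset(sim_preset(b$preset), seed = seed)
  res <- run_association(ds, trait = b$trait, tests = c("T1", "T5", "VT"),
                         n_perm = 999, seed = seed + 1L)
  ev <- run_evaluation(res, causal_genes = ds$causal_genes)
  for (tn in c("T1", "T5", "VT")) {
    summ[[paste(tag, tn)]] <- data.frame(
      architecture = tag, test = tn,
      tpp_at_fpp05 = tpp_at_fpp(ev$roc[[tn]], 0.05),
      tpp_at_fpp10 = tpp_at_fpp(ev$roc[[tn]], 0.10),
      auc = ev$summary$auc[ev$summary$test == tn],
      universe_size = ev$summary$universe_size[ev$summary$test == tn])
    roc <- ev$roc[[tn]]
    rocs[[paste(tag, tn)]] <- cbind(architecture = tag, test = tn,
                                    roc[!is.na(roc$alpha), ])
  }
}
summ <- do.call(rbind, c(summ, list(make.row.names = FALSE)))
write.table(format(summ, digits = 4), "results/power_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(format(do.call(rbind, c(rocs, list(make.row.names = FALSE))),
                   digits = 4),
            "results/roc_points.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
print(summ, row.names = FALSE, digits = 3)
cat("\nNo test dominates: T5 wins when every signal is rare, VT wins when a",
    "\ncommon causal variant hides above the fixed thresholds.\n")
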