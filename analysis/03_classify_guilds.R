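#!/usr/bin/env Rscript
# Step 3 — assign each OTU to a microbial guild.
#
# Known syntrophs and methanogens are recognized from their lineage strings;
# the remaining OTUs split on the sign of the estimated net growth rate:
# positive -> fermenter, negative -> feed-sludge (WAS) associated. Appends
# guild columns to each growth table and checks the calls against the
# simulator's ground truth.

suppressPackageStartupMessages(library(egmb))

rules <- default_rules()
print(rules)

fixdir <- c(control = "results/fixture_control")
sweep <- list.files("results/fixture_srt_sweep", "^truth_.*tsv$")
for (f in sweep)
  fixdir[[sub("^truth_(.*)\\.tsv$", "\\1", f)]] <- "results/fixture_srt_sweep"

for (label in names(fixdir)) {
  g <- utils::read.delim(file.path("results",
                                   paste0("growth_", label, ".tsv")))
  g$mu <- g$mu_per_day
  cl <- classify_guilds(g, rules)
  utils::write.table(cl, file.path("results",
                                   paste0("guilds_", label, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- utils::read.delim(file.path(fixdir[[label]],
                                       paste0("truth_", label, ".tsv")))
  mu_true <- truth$mu_true[match(cl$otu_id, truth$otu_id)]
  est <- cl$status == "estimated"
  ok_sign <- ifelse(mu_true > 0,
                    cl$guild %in% c("fermenter", "syntroph", "methanogen"),
                    cl$guild %in% c("was_associated", "syntroph",
                                    "methanogen"))
  cat(sprintf("%-12s guilds: %s | truth-consistent: %d/%d\n", label,
              paste(names(table(cl$guild)), table(cl$guild),
                    sep = "=", collapse = " "),
              sum(ok_sign[est]), sum(est)))
}
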