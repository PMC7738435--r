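#!/usr/bin/env Rscript
# Step 5 — combined summary: guild-level growth-rate patterns across SRT.
#
# For each reactor, keeps the top eight most abundant OTUs per guild and
# tabulates how estimated rates sit against the 1/SRT ceiling; across the
# SRT sweep, summarizes the mean rate per guild so the SRT response of each
# guild is visible in one table.

suppressPackageStartupMessages(library(egmb))

guild_files <- list.files("results", "^guilds_.*tsv$", full.names = TRUE)
stopifnot(length(guild_files) > 0)

reps <- list()
summaries <- list()
for (f in guild_files) {
  label <- sub("^guilds_(.*)\\.tsv$", "\\1", basename(f))
  cl <- utils::read.delim(f)
  cl$mu <- cl$mu_per_day
  top <- top_representatives(cl, n = 8)
  top$reactor <- label
  reps[[label]] <- top
  est <- cl[cl$status == "estimated", ]
  s <- aggregate(mu ~ guild, est, mean)
  s$reactor <- label
  summaries[[label]] <- s
}
top_all <- do.call(rbind, reps)
utils::write.table(top_all, "results/report_top_otus.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
sum_all <- do.call(rbind, summaries)
wide <- reshape(sum_all, idvar = "guild", timevar = "reactor",
                direction = "wide")
names(wide) <- sub("^mu\\.", "mean_mu_", names(wide))
utils::write.table(wide, "results/report_guild_rates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Mean estimated net growth rate [1/d] per guild and reactor:\n")
print(wide, row.names = FALSE)
cat("\nTop-8 representatives per guild written to results/report_top_otus.tsv\n")
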