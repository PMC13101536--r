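#!/usr/bin/env Rscript
# Stage 2: single-factor and Nemerow composite pollution indices per sample,
# and their relationship to distance from the urban center.

suppressMessages(library(amfassembly))

md <- read_metadata("results/study/metadata.csv")
bg_df <- read.csv("results/study/backgrounds.csv")
backgrounds <- setNames(bg_df$background, bg_df$element)

pol <- pollution_indices(md, backgrounds)
dir.create("results", showWarnings = FALSE)
write.table(pol, "results/pollution.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

rho <- cor(md$distance_km, pol$Pn, method = "spearman")
cat(sprintf("Nemerow Pn: mean %.2f, range %.2f-%.2f; %d/%d samples polluted (Pn > 1)\n",
            mean(pol$Pn), min(pol$Pn), max(pol$Pn), sum(pol$polluted), nrow(pol)))
cat(sprintf("Spearman rho(distance, Pn) = %.2f -> pollution %s with distance\n",
            rho, if (rho < 0) "decreases" else "increases"))
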