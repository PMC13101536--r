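#!/usr/bin/env Rscript
# Stage 5: what drives the balance of assembly processes? Links the betaNTI
# tables from stage 4 to pollution: OLS of betaNTI on the pairwise-mean
# Nemerow index and Spearman correlations with each metal, per community.

suppressMessages(library(amfassembly))

pol <- read.table("results/pollution.tsv", header = TRUE, sep = "\t")
md <- read_metadata("results/study/metadata.csv")

for (g in c("all", "generalist", "specialist")) {
  f <- file.path("results/pipeline", paste0("bnti_", g, ".tsv"))
  if (!file.exists(f)) next
  bn <- read.table(f, header = TRUE, sep = "\t")
  fit <- tryCatch(bnti_vs_pollution(bn, pol), error = function(e) NULL)
  if (!is.null(fit))
    cat(sprintf("%-10s betaNTI ~ Pn: slope %.3f, R2 = %.3f, p = %.3g %s (n = %d)\n",
                g, fit$slope, fit$r_squared, fit$p_value,
                significance_stars(fit$p_value), fit$n))
  sp <- tryCatch(bnti_vs_covariates(bn, md), error = function(e) NULL)
  if (!is.null(sp)) {
    sig <- sp[sp$p_value < 0.05 & !is.na(sp$p_value), ]
    cat(sprintf("%-10s metals with significant Spearman rho vs betaNTI: %s\n", g,
                if (nrow(sig)) paste(sprintf("%s (%.2f%s)", sig$variable,
                                             sig$rho, sig$stars),
                                     collapse = ", ") else "none"))
  }
}
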