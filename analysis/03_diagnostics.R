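#!/usr/bin/env Rscript
# Summarize held-out screening performance (accuracy, sensitivity,
# specificity, false rates) for the fitted suite and check the complement
# identities, writing the diagnostics table in the publication layout.
#
# Usage: Rscript analysis/03_diagnostics.R [--out DIR]
# (expects results/suite_result.rds from analysis/02_fit.R)

suppressPackageStartupMessages(library(diabscreen))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(out = "results")
i <- 1
while (i <= length(args)) {
  opt[[sub("^--", "", args[i])]] <- args[i + 1]; i <- i + 2
}
path <- file.path(opt$out, "suite_result.rds")
if (!file.exists(path)) stop("run analysis/02_fit.R first (missing ", path, ")")
suite_res <- readRDS(path)

d <- suite_res$diagnostics
print(d, digits = 2)
acc <- as.numeric(d[d$metric == "ACC", -1])
tp <- as.numeric(d[d$metric == "TP", -1])
fn <- as.numeric(d[d$metric == "FN", -1])
tn <- as.numeric(d[d$metric == "TN", -1])
fp <- as.numeric(d[d$metric == "FP", -1])
stopifnot(all(abs(tp + fn - 1) < 1e-12, na.rm = TRUE),
          all(abs(tn + fp - 1) < 1e-12, na.rm = TRUE))
cat(sprintf("accuracy across countries: %.2f-%.2f (mean %.2f)\n",
            min(acc, na.rm = TRUE), max(acc, na.rm = TRUE),
            mean(acc, na.rm = TRUE)))
write.csv(d, file.path(opt$out, "diagnostics.csv"), row.names = FALSE, na = "")
cat("wrote", file.path(opt$out, "diagnostics.csv"), "\n")
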