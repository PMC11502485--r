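#!/usr/bin/env Rscript
# Stage 3 — Steiger directionality filter and biological-effect strata.
#
# Steiger removes instruments whose variance explained in the outcome
# exceeds that in the exposure (reverse-causation guards); the survivors
# are stratified by the sign of their indicator-trait association, the
# analog of splitting insulin-raising alleles into resistance (glucose up)
# versus bioaction (glucose down) classes.

library(stratmr)

records <- read.delim("results/harmonized.tsv", stringsAsFactors = FALSE)
truth <- read.delim("results/data/truth.tsv", stringsAsFactors = FALSE)

st <- steiger_filter(records)
write.table(st$results, "results/steiger.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, na = "NA")

removed <- st$results[!st$results$kept, ]
cls <- truth$class[match(removed$variant_id, truth$variant_id)]
cat(sprintf("Steiger removed %d of %d instruments (%d of them truly reverse-causal)\n",
            nrow(removed), nrow(records), sum(cls == "reverse")))

strata <- stratify_by_indicator(st$kept,
                                labels = c(positive = "classA",
                                           negative = "classB"))
print(strata)
sizes <- data.frame(stratum = names(strata$sizes),
                    n = as.integer(strata$sizes))
write.table(sizes, "results/strata.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# how faithful is the observed-sign split to the latent classes?
for (s in c("positive", "negative")) {
  ids <- strata[[s]]$variant_id
  tab <- table(truth$class[match(ids, truth$variant_id)])
  cat(sprintf("  %s stratum (n=%d): %s\n", s, length(ids),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
}
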