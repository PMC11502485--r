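#!/usr/bin/env Rscript
# Stage 4 — causal-effect estimation per stratum.
#
# All four estimators (random-effects IVW, MR-Egger, weighted median,
# penalized weighted median) run on the pooled post-Steiger set and on
# each sign stratum. With class effects of -0.5 and +0.3 the pooled
# estimate is a weight-average that represents neither class — the
# quantitative argument for stratifying before estimating.

library(stratmr)

records <- read.delim("results/harmonized.tsv", stringsAsFactors = FALSE)
kept <- steiger_filter(records)$kept
strata <- stratify_by_indicator(kept, labels = c(positive = "classA",
                                                 negative = "classB"))

sets <- list(all = kept$records, classA = strata$positive,
             classB = strata$negative)
estimates <- do.call(rbind, lapply(names(sets), function(nm) {
  est <- mr_all(sets[[nm]], n_boot = 1000, seed = 20260304)
  est$stratum <- nm
  est
}))
write.table(estimates, "results/estimates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, na = "NA")

ivw <- estimates[estimates$method == "IVW", ]
for (i in seq_len(nrow(ivw))) {
  cat(sprintf("IVW [%s, L=%d]: beta = %+.3f (95%% CI %+.3f to %+.3f), p = %.2g\n",
              ivw$stratum[i], ivw$n_snps[i], ivw$beta[i],
              ivw$beta[i] - 1.96 * ivw$se[i], ivw$beta[i] + 1.96 * ivw$se[i],
              ivw$pval[i]))
}
cat("truth: classA = -0.5, classB = +0.3\n")
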