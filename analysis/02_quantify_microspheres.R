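#!/usr/bin/env Rscript
# Stage 2: absolute perfusion from the microsphere records.
#
# Applies the reference-sample blood-flow equation to every record,
# summarises each group x tissue as mean +/- SEM, and compares groups per
# tissue with one-way ANOVA + Tukey. The ipsilateral-cortex group means are
# the calibration anchors used by stage 3.
# Outputs: results/flows.csv, results/flow_summary.json.

library(cbfautoreg)

cfg <- pipeline_config(seed = 20260101L, out_dir = "results")
quant <- run_quantify(cfg, "results/microspheres.csv")

cat("Basal perfusion, ipsilateral cortex (mean +/- SEM, ml/100 g/min):\n")
s <- quant$summaries
ipsi <- s[s$tissue == "cortex_ipsi", ]
for (i in seq_len(nrow(ipsi)))
  cat(sprintf("  %-8s %6.1f +/- %5.1f (n = %d)\n", ipsi$group[i],
              ipsi$mean[i], ipsi$sem[i], ipsi$n[i]))

ctrl <- ipsi$mean[ipsi$group == "control"]
sah <- ipsi$mean[ipsi$group == "SAH"]
cat(sprintf("SAH reduction vs control: %.1f%%\n", percent_change(ctrl, sah)))

cmp <- quant$comparisons$cortex_ipsi
cat(sprintf("One-way ANOVA (ipsilateral cortex): F = %.2f, p = %.3g\n",
            cmp$f_statistic, cmp$anova_p))
print(cmp)
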