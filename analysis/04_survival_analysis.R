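#!/usr/bin/env Rscript
# Full survival analysis of the staged cohort: demographics by recurrence
# status, Cox models of the EPE parameters (unadjusted and adjusted), the
# seven-group combined-bin model, univariable/multivariable recurrence
# models, and Kaplan-Meier curves by substage and CM-merged group.

library(epestage)

patients <- read_cohort("results/cohort.csv")
report <- run_analysis(patients)
print(report)

write_report(report, "results/report")
message("EPE-parameter models:")
print(report$epe_cox[, c("parameter", "hr", "p_value", "c_index")])
message("log-rank across substages: p = ",
        signif(report$km_substage$logrank_p, 3))
if (!is.null(report$km_cm))
  message("log-rank across CM-merged groups: p = ",
          signif(report$km_cm$logrank_p, 3))
message("wrote results/report/")
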