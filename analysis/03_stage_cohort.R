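#!/usr/bin/env Rscript
# Apply the staging layer to the simulated cohort: combined
# (radial bin, focus number) groups, the three-tier pT3a substage and the
# circumferential-margin combined grouping.

library(epestage)

patients <- read_cohort("results/cohort.csv")
staged <- stage_cohort(patients)
utils::write.csv(staged, "results/staged.csv", row.names = FALSE)

message("substage distribution:")
print(table(staged$substage))
message("combined groups:")
print(table(staged$group))
message("CM-merged groups:")
print(table(staged$cm_merged_group))
message("wrote results/staged.csv")
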