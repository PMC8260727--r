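#!/usr/bin/env Rscript
# Measure the EPE fixtures: radial distance, circumferential length,
# 2D square area and contour shape class for every protrusion, and check
# the recovered values against the construction ground truth.

library(epestage)

fx <- read_geometry_fixture("results/geometry_fixture")
m <- measure_fixture(fx)
truth_r <- vapply(fx$foci, `[[`, numeric(1), "true_r")
truth_w <- vapply(fx$foci, `[[`, numeric(1), "true_w")

m$true_r <- truth_r
m$true_w <- truth_w
utils::write.csv(m, "results/geometry_measures.csv", row.names = FALSE)

message(sprintf("measured %d foci; max |r error| = %.2e mm, max |w error| = %.2e mm",
                nrow(m), max(abs(m$r_mm - truth_r)), max(abs(m$w_mm - truth_w))))
message("shape classes: ",
        paste(names(table(m$shape_class)), table(m$shape_class),
              sep = "=", collapse = ", "))
message("distinct-nodule focus count: ", count_epe_foci(m),
        " (expected ", fx$expected_focus_count, ")")
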