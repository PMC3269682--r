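#!/usr/bin/env Rscript
# Stage 2: scalar elastic-network (GNM) analysis of the dumbbell fixture.
# The slowest non-rigid mode splits the structure into two dynamic domains;
# the thin linker shows the lowest fluctuation and carries the hinge.

library(enmodes)

fixture <- file.path("results", "structures", "dumbbell.pdb")
if (!file.exists(fixture)) stop("run analysis/01_simulate_structures.R first")

cfg <- run_config(input = fixture,
                  domains = list(list("A", 1, 20), list("linker", 21, 24),
                                 list("B", 25, 44)),
                  out_dir = file.path("results", "gnm"))
res <- run_gnm(cfg)

seg <- res$profile$segments
message("per-segment slow-mode fluctuation means:")
print(seg[, c("label", "start", "end", "mean", "max")], row.names = FALSE)
message("hinge nodes (0-based): ",
        paste(res$hinges$hinges, collapse = ", "))
low <- seg$label[which.min(seg$mean)]
message("lowest-fluctuation segment: ", low,
        if (low == "linker") "  (the inter-domain hinge, as expected)")
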