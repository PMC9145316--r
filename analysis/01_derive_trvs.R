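#!/usr/bin/env Rscript
# Hazard characterisation: derive the toxicological reference values for
# the three common-target-organ assessment groups (kidney, liver,
# haematological system) and the reduced-white-blood-cell-count phenomenon
# subgroup, from reference points and default assessment-factor schemes.

suppressPackageStartupMessages(library(tieredmix))

dir.create("results", showWarnings = FALSE)

trvs <- write_trv_table(mycotoxin_reference_points(), "results/trv_table.csv")

cat("Derived", nrow(trvs), "TRVs across",
    length(unique(trvs$group)), "assessment groups\n\n")
print(as.data.frame(trvs), digits = 4)

cat("\nNotable:\n")
cat(" - OTA kidney TRV", signif(trvs$trv[trvs$compound == "OTA"], 2),
    "ug/kg bw/d = BMDL10 4.73 / (10 x 10 x 2)\n")
cat(" - T2/HT2 haematological TRV uses the group TDI 0.02 (critical",
    "effect), not the derived 3.33/200\n")
cat(" - NIV WBC TRV 1.75 re-derived without the 1.5 data-limitation",
    "factor (that factor reflects other endpoints)\n")
cat("\nWrote results/trv_table.csv\n")
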