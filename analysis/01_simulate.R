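#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Two long-term-trial-like experiments are emulated at fixed seeds: a
# loosening-plus-enrichment trial (three maize-like systems plus a wheat-like
# system, n = 6, increments to 200 cm) and a no-till-compaction trial on a
# carbon-rich Mollisol (n = 12, increments to 90 cm), plus a mass-preserving
# compaction null in which the true ESM stock change is zero by construction.

suppressPackageStartupMessages(library(esmsoc))

seed <- 42
out <- "results/profiles"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

century <- generate_profiles(
  c(century_maize_systems(), list(preset("century_wheat_like"))),
  seed = seed)
write_table(century, file.path(out, "century_like.csv"))

wicst <- generate_profiles(preset("wicst_like"), seed = seed + 1L)
write_table(wicst, file.path(out, "wicst_like.csv"))

compaction <- generate_profiles(preset("compaction_null"), seed = seed + 2L)
write_table(compaction, file.path(out, "compaction_null.csv"))

cat("Wrote", file.path(out, c("century_like.csv", "wicst_like.csv",
                              "compaction_null.csv")), sep = "\n  ")
cat("\nPlots simulated:",
    length(unique(century$plot)) + length(unique(wicst$plot)) +
      length(unique(compaction$plot)), "\n")
cat("Surface (0-15 cm) mean BD change, century-like treatments:\n")
surf <- century[century$depth_top_cm == 0, ]
print(round(sapply(split(surf, surf$treatment), function(s)
  mean(s$bd_g_cm3[s$time == "t1"]) - mean(s$bd_g_cm3[s$time == "t0"])), 3))
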