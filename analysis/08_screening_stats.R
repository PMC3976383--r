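#!/usr/bin/env Rscript
## Stage 8 — cohort concordance, penetrance and pedigree consistency.
##
## Applies the recessive concordance model to the packaged 247-dog
## screening panel and the related-breed panel, and checks the simulated
## pedigree against recessive, fully penetrant inheritance.

suppressPackageStartupMessages(library(sinemap))

panel <- load_screening_panel(system.file("extdata", "screening_panel_ts.tsv",
                                          package = "sinemap"))
tab <- concordance(panel)
print(tab)
pen <- penetrance_proxy(panel)
message(sprintf("penetrance proxy: %.1f%% (%d/%d insertion homozygotes affected)",
                pen$pct, pen$cases, pen$hom_ins_total))
write_concordance(tab, "results/concordance_ts.json",
                  "results/concordance_ts.tsv")

message("## related-breed panel")
tt <- load_screening_panel(system.file("extdata", "screening_panel_tt.tsv",
                                       package = "sinemap"))
print(concordance(tt))
write_concordance(concordance(tt), "results/concordance_tt.json",
                  "results/concordance_tt.tsv")

message("## pedigree consistency")
ped <- read_pedigree("results/sim/pedigree.tsv")
v <- pedigree_recessive_check(ped)
message(sprintf("%d dogs, %d violations of the recessive model", nrow(ped),
                nrow(v)))
if (nrow(v) > 0) print(v)
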