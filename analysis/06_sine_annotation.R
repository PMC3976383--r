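#!/usr/bin/env Rscript
## Stage 6 — structural decomposition of the resolved insert.
##
## The full insert sequence (obtained outside the short-read data, e.g. by
## Sanger sequencing across the site) is parsed into SINE body,
## dinucleotide linker and interrupted poly(A) tract.

suppressPackageStartupMessages(library(sinemap))

ins <- readLines("results/sim/insert.fa")[2]
truth <- jsonlite::read_json("results/sim/reads_truth.json")
dec <- decompose_insert(ins, tsd = truth$tsd_seq)
print(dec)
decomposition_to_json(dec, "results/insert_decomposition.json")
decomposition_to_gff(dec, "results/insert_decomposition.gff3")
message("wrote results/insert_decomposition.{json,gff3}")
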