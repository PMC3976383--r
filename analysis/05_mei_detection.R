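#!/usr/bin/env Rscript
## Stage 5 — mobile-element insertion detection from the trio reads.
##
## Reads the simulated SAM, clusters soft-clip breakpoints, pairs them into
## a target-site-duplication call, reconstructs the partial insert ends
## (reads are shorter than the insert) and genotypes the three dogs by
## insertion-supporting read fraction.

suppressPackageStartupMessages(library(sinemap))

reads <- read_sam("results/sim/trio.sam")
ref <- readLines("results/sim/reference.fa")[2]
truth <- jsonlite::read_json("results/sim/reads_truth.json")

calls <- call_insertions(reads, ref)
message(sprintf("%d insertion call(s)", length(calls)))
call <- calls[[1]]
message(sprintf("breakpoints %d/%d (truth %d/%d), TSD %d bp '%s'",
                call$l, call$r, truth$l, truth$r, call$tsd_length,
                call$tsd_sequence))
message(sprintf("partial insert ends: 5' %d nt, 3' %d nt (insert only partly determined)",
                nchar(call$insert_end_5p), nchar(call$insert_end_3p)))
print(call$genotypes)

aff <- reads[reads$sample == "affected", ]
message(sprintf("read-depth step over the TSD in the affected dog: %.2fx flanks",
                tsd_depth_ratio(aff, call)))

write_mei_vcf(calls, "results/mei_calls.vcf", chrom = "chr10",
              reference = ref)
message("wrote results/mei_calls.vcf")
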