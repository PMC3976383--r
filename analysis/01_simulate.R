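#!/usr/bin/env Rscript
## Stage 1 — simulate the study inputs.
##
## Builds the synthetic counterparts of everything the discovery analysis
## consumed: a genotyped case/control cohort with a planted recessive locus
## (18 cases of which 12 carry the mutation, emulating the majority-of-cases
## configuration), a sequenced trio (affected / obligate carrier / control)
## over the insertion locus, the resolved 238 bp insert, and a multi-
## generation recessive pedigree. All downstream stages read these files.

suppressPackageStartupMessages(library(sinemap))
seed <- as.integer(Sys.getenv("SINEMAP_SEED", "1"))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

message("## cohort: 18 cases / 10 controls / 1 obligate carrier, 500 SNPs")
cohort <- gen_cohort(cohort_sim_config(seed = seed))
write_genotypes(cohort$table, "results/sim/cohort.ped",
                "results/sim/cohort.map")
jsonlite::write_json(cohort$truth, "results/sim/cohort_truth.json",
                     auto_unbox = TRUE, digits = NA)
print(cohort$table)
message(sprintf("planted block: %s:%d-%d (causal marker at %d bp)",
                "chr10", cohort$truth$block_start_bp,
                cohort$truth$block_end_bp, cohort$truth$causal_pos))

message("## sequenced trio at 100X, 51 bp reads, 238 bp insert, 14 bp TSD")
sim <- gen_reads(read_sim_config(seed = seed))
write_sam(sim$reads, "results/sim/trio.sam", rname = "chr10",
          ref_len = nchar(sim$reference))
writeLines(c(">chr10_locus", sim$reference), "results/sim/reference.fa")
writeLines(c(">insert_resolved", sim$truth$insert),
           "results/sim/insert.fa")
jsonlite::write_json(sim$truth[c("l", "r", "tsd_len", "tsd_seq")],
                     "results/sim/reads_truth.json", auto_unbox = TRUE,
                     digits = NA)
message(sprintf("%d aligned reads over a %d bp locus; TSD %s at %d-%d",
                nrow(sim$reads), nchar(sim$reference), sim$truth$tsd_seq,
                sim$truth$l, sim$truth$r))

message("## recessive pedigree (3 generations)")
ped <- gen_pedigree(n_generations = 3, founder_carrier_freq = 0.4,
                    n_offspring = 3, seed = seed)
write_pedigree(ped, "results/sim/pedigree.tsv")
message(sprintf("%d dogs, %d affected", nrow(ped),
                sum(ped$status == "case")))
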