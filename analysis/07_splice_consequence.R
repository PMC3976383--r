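#!/usr/bin/env Rscript
## Stage 7 — splice impact and transcript consequences.
##
## Locates the branch point of the affected intron (a non-canonical site
## 76 nt from the acceptor), quantifies its displacement by the insertion,
## then models the downstream consequence of exon-5 skipping on both
## isoforms: frameshift, premature stop, truncated protein, NMD candidacy,
## variant names and in-silico RT-PCR amplicons.

suppressPackageStartupMessages(library(sinemap))
seed <- as.integer(Sys.getenv("SINEMAP_SEED", "1"))

intron <- gen_acceptor_intron(bps_offset = 76, length = 400, seed = seed)
acc <- check_acceptor(substr(intron, nchar(intron) - 9, nchar(intron)))
bps <- find_bps(intron)
message(sprintf("acceptor consensus: match=%s; BPS at %d nt (%s)",
                acc$match, bps$offset,
                ifelse(bps$canonical, "canonical", "non-canonical")))

gm <- gen_gene_model()
impact <- assess_insertion(bps$offset, gm$insertion$upstream_offset,
                           gm$insertion$length)
print(impact)
splice_report_to_json(impact, "results/splice_impact.json")

message("## variant names")
sh <- build_isoform(gm$fl, 4)
message(sprintf("  full-length: %s",
                name_intronic_insertion(gm$fl, 5, 15, 238)))
message(sprintf("  short:       %s",
                name_intronic_insertion(sh, 5, 15, 238)))

message("## exon-5 skip consequences (full-length isoform)")
cons <- compare_isoforms(gm$fl, build_isoform(gm$fl, 5))
print(cons)
jsonlite::write_json(unclass(cons), "results/consequence_fl_skip5.json",
                     auto_unbox = TRUE, digits = NA)

message("## in-silico RT-PCR (primers in exons 3 and 6)")
isoforms <- list(fl = gm$fl, `fl-5` = build_isoform(gm$fl, 5), sh = gm$sh,
                 `sh-5` = build_isoform(gm$sh, 5))
amp <- data.frame(isoform = names(isoforms),
                  amplicon_bp = vapply(isoforms, insilico_rtpcr, integer(1),
                                       fwd = gm$primers$fwd,
                                       rev = gm$primers$rev))
print(amp, row.names = FALSE)
utils::write.table(amp, "results/rtpcr_amplicons.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
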