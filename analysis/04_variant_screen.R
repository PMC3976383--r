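#!/usr/bin/env Rscript
## Stage 4 — segregation- and proximity-filtered variant screen.
##
## Emulates the targeted-resequencing screen over the critical region: a
## panel of candidate variants genotyped on a 10-dog cohort (4 cases, 2
## obligate carriers, 4 controls) is reduced to those that are homozygous
## in every case, heterozygous in every carrier and wildtype in every
## control, then to those in or near an exon of the candidate gene.

suppressPackageStartupMessages(library(sinemap))
seed <- as.integer(Sys.getenv("SINEMAP_SEED", "1"))
set.seed(seed)

gm <- gen_gene_model()
cohort <- data.frame(
  id = sprintf("NGS%02d", 1:10),
  status = rep(c("case", "obligate_carrier", "control"), c(4, 2, 4)),
  stringsAsFactors = FALSE)

## candidate variants across the locus; the causal insertion plus decoys
span <- range(c(gm$fl$exons$gstart, gm$fl$exons$gend))
decoy_pos <- sort(sample(seq(span[1] - 5000, span[2] + 5000), 60))
states <- c("hom_ref", "het", "hom_alt")
gt <- matrix(sample(states, 60 * 10, replace = TRUE), 60,
             dimnames = list(NULL, cohort$id))
## a handful of decoys segregate perfectly but sit deep in introns
perfect <- c("hom_alt", "hom_alt", "hom_alt", "hom_alt", "het", "het",
             "hom_ref", "hom_ref", "hom_ref", "hom_ref")
mid_intron <- gm$fl$exons$gend[1] + c(800, 1100)
for (p in mid_intron) {
  decoy_pos <- c(decoy_pos, p)
  gt <- rbind(gt, perfect)
}
## the causal candidate: 15 nt upstream of the exon-5 acceptor
causal_pos <- gm$insertion$genomic_pos
decoy_pos <- c(decoy_pos, causal_pos)
gt <- rbind(gt, perfect)
ord <- order(decoy_pos)
calls <- variant_calls(
  data.frame(chrom = gm$chrom, pos = decoy_pos[ord], ref = "A", alt = "T",
             stringsAsFactors = FALSE),
  gt[ord, , drop = FALSE])
write_variant_calls(calls, "results/candidates.vcf")
message(sprintf("%d candidate variants", nrow(calls$info)))

seg <- segregation_filter(calls, cohort)
message(sprintf("%d segregate with the phenotype", nrow(seg$info)))
near <- proximity_filter(seg, gm$fl, window_bp = 50)
message(sprintf("%d of those in or near an exon:", nrow(near$info)))
print(near$info)
write_variant_calls(near, "results/segregating_near_exon.vcf")
stopifnot(causal_pos %in% near$info$pos)
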