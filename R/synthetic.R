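rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Cohort simulation configuration
#'
#' Defaults emulate the discovery cohort regime: 18 microsatellite-genotyped
#' cases of which about 65 percent carry the mapped recessive mutation
#' (locus homogeneity 0.65, the majority-of-cases configuration), a handful
#' of controls, one obligate carrier, and a marker panel with a homozygous
#' linkage block around the causal locus.
#'
#' @param n_cases,n_controls,n_obligate_carriers cohort composition
#'   (defaults 18, 10, 1).
#' @param n_markers markers on the simulated chromosome (default 500).
#' @param causal_index marker index of the causal locus (default mid-panel).
#' @param block_halfwidth markers on each side of the causal locus sharing
#'   the mutant haplotype (default 5, an 11-marker block).
#' @param locus_homogeneity probability a case carries two copies of the
#'   mapped mutation; the rest are phenocopies (default 0.65).
#' @param n_subpopulations,divergence stratification structure: number of
#'   subpopulations and the allele-frequency shift between them (defaults 1
#'   and 0).
#' @param control_carrier_rate probability a control or phenocopy carries
#'   one mutant haplotype (default 0.15; never two).
#' @param missing_rate per-call missing probability (default 0.005).
#' @param spacing_bp marker spacing (default 10000).
#' @param seed mandatory RNG seed.
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_cases = 18, n_controls = 10,
                              n_obligate_carriers = 1, n_markers = 500,
                              causal_index = NULL, block_halfwidth = 5,
                              locus_homogeneity = 0.65,
                              n_subpopulations = 1, divergence = 0,
                              control_carrier_rate = 0.15,
                              missing_rate = 0.005, spacing_bp = 10000,
                              seed) {
  if (missing(seed)) stopf("cohort_sim_config: seed is mandatory")
  stopifnot(locus_homogeneity >= 0, locus_homogeneity <= 1,
            missing_rate >= 0, missing_rate <= 1, n_cases >= 1)
  causal_index <- causal_index %||% (n_markers %/% 2)
  if (causal_index - block_halfwidth < 1 ||
      causal_index + block_halfwidth > n_markers)
    stopf("causal block falls outside the marker panel")
  structure(as.list(environment()), class = "cohort_sim_config")
}

#' Simulate a stratified case/control cohort with a recessive locus
#'
#' Haplotype-based simulation: each sample carries two haplotypes drawn from
#' its subpopulation's allele frequencies; mutation-linked haplotypes are
#' additionally homozygous for a fixed allele across the causal block.
#' Cases carry two mutant haplotypes with probability `locus_homogeneity`
#' (otherwise they are phenocopies), obligate carriers exactly one, controls
#' and phenocopies at most one. Full penetrance: phenotype labels follow the
#' sampling arm, and the truth record stores the planted interval.
#'
#' @param config a [cohort_sim_config()].
#' @return list `table` (a [genotype_table()]) and `truth` (causal marker,
#'   block interval, per-sample mutant-haplotype dosage).
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls + config$n_obligate_carriers
  m <- config$n_markers
  status <- c(rep("case", config$n_cases), rep("control", config$n_controls),
              rep("obligate_carrier", config$n_obligate_carriers))
  ids <- sprintf("%s%02d", c("TS_CASE_", "TS_CTRL_", "TS_CARR_")[
    match(status, STATUS_LEVELS[c(1, 2, 3)])], seq_len(n))
  subpop <- sample.int(config$n_subpopulations, n, replace = TRUE)
  p_base <- stats::runif(m, 0.1, 0.9)
  ## the disease-linked allele is uncommon on population haplotypes
  block0 <- (config$causal_index - config$block_halfwidth):
    (config$causal_index + config$block_halfwidth)
  p_base[block0] <- stats::runif(length(block0), 0.1, 0.4)
  shift <- matrix(stats::runif(m * config$n_subpopulations, -1, 1) *
                    config$divergence, m)
  p_sub <- pmin(pmax(p_base + shift, 0.02), 0.98)   # m x K, freq of allele A
  block <- (config$causal_index - config$block_halfwidth):
    (config$causal_index + config$block_halfwidth)
  ## emulate the printed 12-of-18 configuration: a fixed rounded count of
  ## mutation-homozygous cases, assigned at random
  n_hom <- round(config$locus_homogeneity * config$n_cases)
  if (n_hom > config$n_cases) stopf("more homogeneous cases than cases")
  hom_case <- rep(FALSE, n)
  hom_case[sample(which(status == "case"), n_hom)] <- TRUE
  n_mut_hap <- ifelse(hom_case, 2L,
                      ifelse(status == "obligate_carrier", 1L,
                             ifelse(stats::runif(n) <
                                      config$control_carrier_rate, 1L, 0L)))
  draw_hap <- function(k) ifelse(stats::runif(m) < p_sub[, k], "A", "B")
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  for (i in seq_len(n)) {
    h1 <- draw_hap(subpop[i]); h2 <- draw_hap(subpop[i])
    if (n_mut_hap[i] >= 1) h1[block] <- "A"
    if (n_mut_hap[i] == 2) h2[block] <- "A"
    if (n_mut_hap[i] == 1) h2[config$causal_index] <- "B"  # het at the locus
    a1[i, ] <- h1; a2[i, ] <- h2
  }
  miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
  a1[miss] <- NA; a2[miss] <- NA
  pos <- seq(1000000L, by = as.integer(config$spacing_bp), length.out = m)
  markers <- data.frame(id = sprintf("M%04d", seq_len(m)), chrom = "chr10",
                        pos = pos, kind = "SNP", stringsAsFactors = FALSE)
  samples <- data.frame(id = ids, status = status, breed = "TS",
                        subpop = subpop, stringsAsFactors = FALSE)
  list(table = genotype_table(samples, markers, a1, a2),
       truth = list(causal_index = config$causal_index,
                    causal_pos = pos[config$causal_index],
                    block_start_bp = pos[block[1]],
                    block_end_bp = pos[block[length(block)]],
                    n_mut_hap = stats::setNames(n_mut_hap, ids),
                    hom_cases = ids[hom_case]))
}

#' Generate a SINE-architecture insert sequence
#'
#' Builds body + (CT)xcopies + interrupted poly(A), 5' to 3'. Defaults
#' reproduce the observed allele's architecture: a 132 bp SINE body, eight
#' CT copies and a 45 bp poly(A) tract interrupted by occasional single
#' T's (never two adjacent, first base always A). The body is random
#' non-repetitive sequence whose last two bases are kept distinct from the
#' linker unit so the planted copy number is well defined.
#'
#' @param body_len SINE body length (default 132).
#' @param repeat_copies CT copies (default 8).
#' @param polya_len poly(A) tract length including interruptions
#'   (default 45).
#' @param interrupt_rate per-base probability of a T interruption
#'   (default 0.04, capped so the tract stays above 90 percent A).
#' @param seed RNG seed.
#' @return character insert sequence of length
#'   `body_len + 2 * repeat_copies + polya_len`.
#' @export
gen_insert <- function(body_len = 132, repeat_copies = 8, polya_len = 45,
                       interrupt_rate = 0.04, seed) {
  stopifnot(body_len >= 0, repeat_copies >= 0, polya_len >= 0)
  set.seed(seed)
  body <- if (body_len > 0) rand_dna(body_len) else ""
  while (body_len >= 2 &&
         substr(body, body_len - 1, body_len) == "CT") {
    body <- paste0(substr(body, 1, body_len - 2), rand_dna(2))
  }
  linker <- strrep("CT", repeat_copies)
  pa <- rep("A", polya_len)
  if (polya_len >= 3 && interrupt_rate > 0) {
    max_int <- max(0L, ceiling(0.1 * (polya_len + 1)) - 2L)
    cand <- which(stats::runif(polya_len) < interrupt_rate)
    cand <- cand[cand > 1 & cand < polya_len]
    cand <- cand[c(TRUE, diff(cand) > 1)]
    if (length(cand) > max_int) cand <- cand[seq_len(max_int)]
    pa[cand] <- "T"
  }
  paste0(body, linker, paste(pa, collapse = ""))
}

#' Read-simulation configuration
#'
#' Defaults follow the targeted-resequencing regime: 51 bp paired reads at
#' about 100X over a locus carrying a 238 bp insert (132 bp body, (CT)8,
#' 90 bp interrupted poly(A)) flanked by a 14 bp target-site duplication —
#' an insert longer than the read, so only partial ends are recoverable.
#'
#' @param ref_len reference length (default 4000).
#' @param ins_site 5' reference position of the duplicated motif
#'   (default 2000).
#' @param tsd_len target-site duplication length (default 14).
#' @param insert insert sequence (default `gen_insert(polya_len = 90)`,
#'   238 bp).
#' @param read_len read length (default 51).
#' @param depth mean per-sample depth (default 100).
#' @param genotypes named character vector sample -> `hom_ins`/`het`/
#'   `hom_ref`.
#' @param min_map minimum aligned bases for a read to be mapped (default 8).
#' @param subst_rate uniform substitution error rate (default 0).
#' @param seed mandatory RNG seed.
#' @return list of class `read_sim_config`.
#' @export
read_sim_config <- function(ref_len = 4000, ins_site = 2000, tsd_len = 14,
                            insert = NULL, read_len = 51, depth = 100,
                            genotypes = c(affected = "hom_ins",
                                          carrier = "het",
                                          control = "hom_ref"),
                            min_map = 8, subst_rate = 0, seed) {
  if (missing(seed)) stopf("read_sim_config: seed is mandatory")
  insert <- insert %||% gen_insert(polya_len = 90, seed = seed + 101L)
  stopifnot(ins_site + tsd_len - 1 < ref_len, read_len >= 2 * min_map)
  structure(as.list(environment()), class = "read_sim_config")
}

#' Simulate aligned reads over an insertion locus
#'
#' Draws reads per haplotype (a homozygote's haplotypes both carry the
#' insert, a heterozygote's one, a wildtype sample's none) at Poisson depth
#' and computes each read's alignment against the reference analytically:
#' on the insertion haplotype the duplicated motif appears on both sides of
#' the insert, reads crossing an insertion junction are soft-clipped at the
#' motif edge, reads entirely inside the insert are unmapped, and reads with
#' fewer than `min_map` aligned bases are dropped.
#'
#' @param config a [read_sim_config()].
#' @return list `reads` (an [aligned_reads()] table over all samples),
#'   `reference` (character) and `truth` (breakpoints `l`, `r`, TSD and
#'   insert sequences).
#' @export
gen_reads <- function(config) {
  stopifnot(inherits(config, "read_sim_config"))
  set.seed(config$seed)
  rl <- config$read_len
  ref <- rand_dna(config$ref_len)
  L <- config$ins_site; R <- L + config$tsd_len - 1L
  ins <- toupper(config$insert); ni <- nchar(ins)
  hap_ins <- paste0(substr(ref, 1, R), ins, substr(ref, L, config$ref_len))
  out <- list()
  for (smp in names(config$genotypes)) {
    gt <- config$genotypes[[smp]]
    haps <- switch(gt, hom_ins = c(TRUE, TRUE), het = c(TRUE, FALSE),
                   hom_ref = c(FALSE, FALSE),
                   stopf("unknown genotype %s", gt))
    for (h in seq_along(haps)) {
      with_insert <- haps[h]
      hap_len <- if (with_insert) nchar(hap_ins) else config$ref_len
      n_reads <- stats::rpois(1, hap_len * config$depth / (2 * rl))
      if (n_reads == 0) next
      starts <- sample.int(hap_len - rl + 1L, n_reads, replace = TRUE)
      ends <- starts + rl - 1L
      seqs <- substring(if (with_insert) hap_ins else ref, starts, ends)
      if (config$subst_rate > 0) seqs <- mutate_seqs(seqs, config$subst_rate)
      if (!with_insert) {
        df <- data.frame(pos = starts, end = ends, lclip = 0L, rclip = 0L,
                         lseq = "", rseq = "", seq = seqs,
                         stringsAsFactors = FALSE)
      } else {
        left_flank <- ends <= R
        right_flank <- starts >= R + ni + 1L
        inside <- starts > R & ends <= R + ni
        cross5 <- starts <= R & ends > R & !inside
        cross3 <- starts > R & starts <= R + ni & ends > R + ni
        both <- cross5 & ends > R + ni      # short inserts only
        cross5[both] <- (R - starts[both] + 1L) >= (ends[both] - R - ni)
        cross3 <- (cross3 | both) & !cross5
        pos <- integer(n_reads); endr <- integer(n_reads)
        lclip <- integer(n_reads); rclip <- integer(n_reads)
        lseq <- character(n_reads); rseq <- character(n_reads)
        pos[left_flank] <- starts[left_flank]
        endr[left_flank] <- ends[left_flank]
        pos[right_flank] <- starts[right_flank] - ni - config$tsd_len
        endr[right_flank] <- ends[right_flank] - ni - config$tsd_len
        pos[cross5] <- starts[cross5]
        endr[cross5] <- R
        rclip[cross5] <- ends[cross5] - R
        rseq[cross5] <- substring(hap_ins, R + 1L, ends[cross5])
        pos[cross3] <- L
        endr[cross3] <- L + (ends[cross3] - (R + ni)) - 1L
        lclip[cross3] <- (R + ni) - starts[cross3] + 1L
        lseq[cross3] <- substring(hap_ins, starts[cross3], R + ni)
        keep <- !inside & (endr - pos + 1L) >= config$min_map
        df <- data.frame(pos = pos, end = endr, lclip = lclip,
                         rclip = rclip, lseq = lseq, rseq = rseq, seq = seqs,
                         stringsAsFactors = FALSE)[keep, , drop = FALSE]
      }
      if (nrow(df) > 0) {
        df$sample <- smp
        df$qname <- sprintf("%s_h%d_%04d", smp, h, seq_len(nrow(df)))
        out[[length(out) + 1]] <- df
      }
    }
  }
  reads <- do.call(rbind, out)
  reads <- reads[order(reads$pos), ]
  rownames(reads) <- NULL
  list(reads = aligned_reads(reads), reference = ref,
       truth = list(l = L, r = R, tsd_len = config$tsd_len,
                    tsd_seq = substr(ref, L, R), insert = ins))
}

mutate_seqs <- function(seqs, rate) {
  vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(b)) < rate
    if (any(hit))
      b[hit] <- vapply(b[hit], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Mendelian offspring genotypes
#' @param sire_gt,dam_gt parental genotypes (`hom_ins`/`het`/`hom_wt`).
#' @param n number of offspring.
#' @return character vector of offspring genotypes.
#' @export
mendelian_offspring <- function(sire_gt, dam_gt, n) {
  gamete <- function(gt, n) switch(gt,
                                   hom_ins = rep(1L, n),
                                   hom_wt = rep(0L, n),
                                   het = stats::rbinom(n, 1, 0.5),
                                   stopf("unknown genotype %s", gt))
  dose <- gamete(sire_gt, n) + gamete(dam_gt, n)
  c("hom_wt", "het", "hom_ins")[dose + 1L]
}

#' Simulate a recessive-trait pedigree
#'
#' Forward simulation: founder mates are heterozygous carriers with
#' probability `founder_carrier_freq` (otherwise homozygous wildtype),
#' matings transmit alleles Mendelianly, and the trait is fully penetrant
#' recessive (affected iff insertion-homozygous). Each non-founder lineage
#' member mates with a fresh founder each generation.
#'
#' @param n_generations generations below the founders (default 3).
#' @param founder_carrier_freq carrier probability among founders
#'   (default 0.3).
#' @param n_offspring offspring per mating (default 3).
#' @param seed RNG seed.
#' @return a [as_pedigree()] data.frame with genotype and status columns.
#' @export
gen_pedigree <- function(n_generations = 3, founder_carrier_freq = 0.3,
                         n_offspring = 3, seed) {
  stopifnot(n_generations >= 1, n_offspring >= 1)
  set.seed(seed)
  founder_gt <- function(n)
    ifelse(stats::runif(n) < founder_carrier_freq, "het", "hom_wt")
  rows <- data.frame(id = c("F001", "F002"), sire = NA, dam = NA,
                     genotype = founder_gt(2), stringsAsFactors = FALSE)
  counter <- 2L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("F%03d", counter)
  }
  parents <- list(c("F001", "F002"))
  for (g in seq_len(n_generations)) {
    next_parents <- list()
    for (pr in parents) {
      sg <- rows$genotype[rows$id == pr[1]]
      dg <- rows$genotype[rows$id == pr[2]]
      kids_gt <- mendelian_offspring(sg, dg, n_offspring)
      for (k in seq_len(n_offspring)) {
        kid <- new_id()
        rows <- rbind(rows, data.frame(id = kid, sire = pr[1], dam = pr[2],
                                       genotype = kids_gt[k],
                                       stringsAsFactors = FALSE))
        if (g < n_generations && k == 1) {
          mate <- new_id()
          rows <- rbind(rows, data.frame(id = mate, sire = NA, dam = NA,
                                         genotype = founder_gt(1),
                                         stringsAsFactors = FALSE))
          next_parents[[length(next_parents) + 1]] <- c(kid, mate)
        }
      }
    }
    parents <- next_parents
  }
  rows$status <- ifelse(rows$genotype == "hom_ins", "case", "control")
  as_pedigree(rows[, c("id", "sire", "dam", "status", "genotype")])
}

#' Build the toy six-exon gene model
#'
#' A synthetic two-isoform gene model satisfying, simultaneously, the
#' printed constraints of the mapped retinal gene: the full-length isoform
#' translates to 716 aa and the exon-4-skipped short isoform to 660 aa
#' (exon 4 is 168 nt, three times the 56 aa difference), the exon-5 acceptor
#' sits at coding position 1758 in the full-length and 1590 in the short
#' isoform, exon 5 is 100 nt, and primers in exons 3 and 6 amplify
#' 421/321/253/153 bp across the four isoforms. The coding sequence is
#' synthetic (deterministically chosen so that exon-5 skipping frameshifts
#' into a premature stop); every constraint is asserted at build time.
#' Genomic exon coordinates place the locus on chr10 with the insertion site
#' 15 nt upstream of the exon-5 acceptor.
#'
#' @return list `fl`, `sh` ([transcript_model()]s), `primers` (fwd/rev),
#'   `insertion` (exon, upstream_offset, length, genomic_pos), `chrom`.
#' @export
gen_gene_model <- function() {
  exon_len <- c(489L, 600L, 500L, 168L, 100L, 400L)
  intron_len <- c(2000L, 1500L, 1200L, 900L, 1100L)
  g0 <- 64960000L
  gstart <- integer(6); gend <- integer(6)
  at <- g0
  for (i in 1:6) {
    gstart[i] <- at
    gend[i] <- at + exon_len[i] - 1L
    at <- gend[i] + 1L + if (i < 6) intron_len[i] else 0L
  }
  exons <- data.frame(id = 1:6, length = exon_len, gstart = gstart,
                      gend = gend)
  n_aa <- 716L
  utr3 <- sum(exon_len) - (3L * (n_aa + 1L))
  sense <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], "ATG")
  build <- function(seed) {
    set.seed(seed)
    coding <- paste0("ATG", paste(sample(sense, n_aa - 1L, replace = TRUE),
                                  collapse = ""), "TAA")
    transcript_model(exons, cds_start = 1L, label = "fl",
                     sequence = paste0(coding, rand_dna(utr3)))
  }
  fl <- NULL
  with_preserved_rng({
    for (seed in 1:50) {
      cand <- build(seed)
      sh <- build_isoform(cand, 4)
      ok <- translate_and_scan(cand)$protein_length == 716L &&
        translate_and_scan(sh)$protein_length == 660L &&
        !translate_and_scan(build_isoform(cand, 5))$nonstop &&
        translate_and_scan(build_isoform(cand, 5))$protein_length < 716L &&
        !translate_and_scan(build_isoform(sh, 5))$nonstop &&
        translate_and_scan(build_isoform(sh, 5))$protein_length < 660L
      if (ok) {
        fl <- cand
        break
      }
    }
  })
  if (is.null(fl)) stopf("gene model constraints could not be satisfied")
  sh <- build_isoform(fl, 4)
  sh$label <- "sh"
  primers <- list(fwd = list(exon = 3, offset = 421L),
                  rev = list(exon = 6, offset = 73L))
  stopifnot(
    map_coding_position(fl, 5) == 1758L,
    map_coding_position(sh, 5) == 1590L,
    3L * (716L - 660L) == 1758L - 1590L,
    insilico_rtpcr(fl, primers$fwd, primers$rev) == 421L,
    insilico_rtpcr(build_isoform(fl, 5), primers$fwd, primers$rev) == 321L,
    insilico_rtpcr(sh, primers$fwd, primers$rev) == 253L,
    insilico_rtpcr(build_isoform(sh, 5), primers$fwd, primers$rev) == 153L)
  list(fl = fl, sh = sh, primers = primers,
       insertion = list(exon = 5L, upstream_offset = 15L, length = 238L,
                        genomic_pos = gstart[5] - 15L),
       chrom = "chr10")
}

#' Build an intron fixture with a single displaced branch point
#'
#' Deterministic intron whose only branch-point consensus match has its
#' branch A at `bps_offset` nt from the last intron base, with none inside
#' the canonical 20-50 nt window, and whose 3' end is the literal acceptor
#' consensus `TTTCTTACAG`. The background alphabet excludes T outside the
#' planted motif and the acceptor tail, so no spurious motif (which requires
#' a T) can arise.
#'
#' @param bps_offset branch-A offset in nt (default 76).
#' @param length intron length (default 400).
#' @param seed RNG seed (default 1).
#' @return character intron sequence.
#' @export
gen_acceptor_intron <- function(bps_offset = 76, length = 400, seed = 1) {
  stopifnot(length >= bps_offset + 10)
  with_preserved_rng({
    set.seed(seed)
    b <- strsplit(rand_dna(length, alphabet = c("A", "C", "G")), "")[[1]]
    a_pos <- length - bps_offset + 1L
    b[(a_pos - 5L):(a_pos + 1L)] <- c("C", "T", "C", "T", "G", "A", "C")
    b[(length - 9L):length] <- strsplit("TTTCTTACAG", "")[[1]]
    paste(b, collapse = "")
  })
}
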