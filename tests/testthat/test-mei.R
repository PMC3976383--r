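test_that("clip clustering finds modal breakpoints and ignores short clips", {
  expect_equal(collect_clip_clusters(aligned_reads(read_row("s", 1, 51))),
               list(right = list(), left = list()))
  set.seed(55)
  rows <- do.call(rbind, lapply(1:30, function(i) {
    bp <- 1000L + sample(c(-1L, 0L, 0L, 1L), 1)
    read_row("s", bp - 40L, bp, rclip = 10, rseq = "GGGTTCCAAG")
  }))
  cl <- collect_clip_clusters(aligned_reads(rows))
  expect_length(cl$right, 1)
  expect_length(cl$left, 0)
  expect_equal(cl$right[[1]]$n, 30L)
  ## modal breakpoint = plurality position
  tab <- table(rows$end)
  expect_equal(cl$right[[1]]$breakpoint,
               as.integer(names(tab)[which.max(tab)]))
  ## clips below min_clip are not evidence
  weak <- aligned_reads(read_row("s", 100, 150, rclip = 3, rseq = "AAA"))
  expect_length(collect_clip_clusters(weak)$right, 0)
})

test_that("a homozygous insertion sample shows exactly one cluster per side", {
  sim <- gen_reads(read_sim_config(ref_len = 2000, ins_site = 1000,
                                   genotypes = c(aff = "hom_ins"),
                                   seed = 21))
  cl <- collect_clip_clusters(sim$reads)
  expect_length(cl$right, 1)
  expect_length(cl$left, 1)
  expect_equal(cl$right[[1]]$breakpoint, sim$truth$r)
  expect_equal(cl$left[[1]]$breakpoint, sim$truth$l)
})

test_that("breakpoint pairing applies the TSD length bounds", {
  mk <- function(rbp, lbp) list(
    right = list(list(breakpoint = rbp, positions = rbp, seqs = "AAAA", n = 1)),
    left = list(list(breakpoint = lbp, positions = lbp, seqs = "CCCC", n = 1)))
  ref <- strrep("ACGT", 500)
  calls <- pair_breakpoints(mk(1013L, 1000L), 4, 30, ref)
  expect_length(calls, 1)
  expect_equal(calls[[1]]$tsd_length, 14L)
  expect_equal(calls[[1]]$tsd_sequence, substr(ref, 1000, 1013))
  expect_length(pair_breakpoints(mk(1500L, 1000L), 4, 30, ref), 0)
})

test_that("planted TSD lengths 4, 10 and 30 are recovered exactly", {
  for (tsd in c(4L, 10L, 30L)) {
    sim <- gen_reads(read_sim_config(ref_len = 2000, ins_site = 1000,
                                     tsd_len = tsd,
                                     genotypes = c(aff = "hom_ins"),
                                     seed = 300 + tsd))
    calls <- call_insertions(sim$reads, sim$reference)
    expect_length(calls, 1)
    expect_equal(calls[[1]]$tsd_length, tsd)
    expect_equal(calls[[1]]$tsd_sequence, sim$truth$tsd_seq)
  }
})

test_that("insert-end consensus recovers the generator's partial ends", {
  ## identical tails: consensus is the tail
  cons <- sinemap:::clip_consensus(rep("GGGTTCC", 10))
  expect_equal(cons$seq, "GGGTTCC")
  expect_false(cons$low_confidence)
  ## single read: flagged low-confidence
  single <- sinemap:::clip_consensus("ACGTACGT")
  expect_true(single$low_confidence)
  ## a 238 bp insert with 51 bp reads: ends recovered, never the full insert
  sim <- gen_reads(read_sim_config(ref_len = 2000, ins_site = 1000,
                                   genotypes = c(aff = "hom_ins"),
                                   seed = 22))
  call <- call_insertions(sim$reads, sim$reference)[[1]]
  expect_lte(nchar(call$insert_end_5p), 43)
  expect_lte(nchar(call$insert_end_3p), 43)
  expect_gt(nchar(call$insert_end_5p), 20)
  expect_true(startsWith(sim$truth$insert, call$insert_end_5p))
  expect_true(endsWith(sim$truth$insert, call$insert_end_3p))
  expect_lt(nchar(call$insert_end_5p) + nchar(call$insert_end_3p),
            nchar(sim$truth$insert))
})

test_that("per-column majority survives a dissenting read", {
  tails <- c(rep("ACGTACGT", 7), "ACGAACGT", "TCGTACGT", "ACGTACGA")
  cons <- sinemap:::clip_consensus(tails, min_agreement = 0.6)
  expect_equal(cons$seq, "ACGTACGT")
})

test_that("read-support genotyping applies the VAF thresholds", {
  ## zero supporting, 60 spanning -> vaf 0, hom_ref
  span <- do.call(rbind, lapply(1:60, function(i)
    read_row("ctl", 980L, 1030L)))
  call <- list(l = 1000L, r = 1013L, tsd_length = 14L)
  g <- genotype_insertion(call, aligned_reads(span))$genotypes
  expect_equal(g$vaf, 0)
  expect_equal(g$genotype, "hom_ref")
  expect_equal(g$spanning_reads, 60L)
  ## no coverage -> no_call with flag
  off <- aligned_reads(read_row("ctl", 1L, 51L))
  g0 <- genotype_insertion(call, off)$genotypes
  expect_equal(g0$genotype, "no_call")
  expect_true(g0$zero_coverage)
  ## vaf is invariant to read order
  sim <- gen_reads(read_sim_config(ref_len = 2000, ins_site = 1000,
                                   seed = 23))
  cl <- call_insertions(sim$reads, sim$reference)[[1]]
  shuf <- sim$reads[sample(nrow(sim$reads)), ]
  g1 <- genotype_insertion(cl, sim$reads)$genotypes
  g2 <- genotype_insertion(cl, aligned_reads(shuf))$genotypes
  expect_equal(g1$vaf, g2$vaf)
  expect_equal(g1$genotype, c("hom_ins", "hom_ref", "het")[
    match(g1$sample, c("affected", "control", "carrier"))])
})

test_that("the TSD shows the duplication read-depth step in a homozygote", {
  sim <- gen_reads(read_sim_config(ref_len = 2000, ins_site = 1000,
                                   genotypes = c(aff = "hom_ins"),
                                   seed = 24))
  call <- call_insertions(sim$reads, sim$reference)[[1]]
  ratio <- tsd_depth_ratio(sim$reads, call)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})

test_that("SAM text and the symbolic insertion VCF round-trip the caller's fields", {
  sim <- gen_reads(read_sim_config(ref_len = 2000, ins_site = 1000,
                                   depth = 30, seed = 25))
  f <- tempfile(fileext = ".sam")
  write_sam(sim$reads, f, rname = "chr10", ref_len = 2000)
  back <- read_sam(f)
  expect_equal(nrow(back), nrow(sim$reads))
  o1 <- sim$reads[order(sim$reads$qname), ]
  o2 <- back[order(back$qname), ]
  expect_equal(o2$pos, o1$pos)
  expect_equal(o2$lclip, o1$lclip)
  expect_equal(o2$rclip, o1$rclip)
  expect_equal(o2$rseq, o1$rseq)
  expect_equal(o2$sample, o1$sample)

  calls <- call_insertions(sim$reads, sim$reference)
  v <- tempfile(fileext = ".vcf")
  write_mei_vcf(calls, v, chrom = "chr10", reference = sim$reference)
  lines <- readLines(v)
  rec <- lines[!startsWith(lines, "#")]
  expect_length(rec, 1)
  expect_match(rec, "TSDLEN=14")
  expect_match(rec, sprintf("TSDSEQ=%s", sim$truth$tsd_seq))
  expect_match(rec, "<INS>")
})
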