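test_that("the toy gene model satisfies every printed constraint at once", {
  gm <- gen_gene_model()
  expect_equal(translate_and_scan(gm$fl)$protein_length, 716L)
  expect_equal(translate_and_scan(gm$sh)$protein_length, 660L)
  expect_equal(map_coding_position(gm$fl, 5), 1758L)
  expect_equal(map_coding_position(gm$sh, 5), 1590L)
  expect_equal(gm$fl$exons$length[4], 168L)
  expect_equal(gm$fl$exons$length[5], 100L)
  expect_identical(3L * (716L - 660L), 1758L - 1590L)
  ## deterministic: two builds are identical
  expect_equal(gen_gene_model()$fl$sequence, gm$fl$sequence)
})

test_that("isoform construction remaps coordinates and sequence together", {
  gm <- gen_gene_model()
  expect_equal(build_isoform(gm$fl, NULL)$sequence, gm$fl$sequence)
  sh <- build_isoform(gm$fl, 4)
  expect_equal(nchar(sh$sequence), nchar(gm$fl$sequence) - 168L)
  expect_equal(translate_and_scan(sh)$protein_length, 716L - 56L)
  expect_error(build_isoform(gm$fl, 1), "translation start")
  expect_error(build_isoform(gm$fl, 9), "unknown exon")

  ## random models: post-skip exon starts equal a cumulative-sum oracle
  set.seed(81)
  for (r in 1:25) {
    n_ex <- sample(3:8, 1)
    lens <- sample(30:300, n_ex, replace = TRUE)
    model <- transcript_model(data.frame(id = seq_len(n_ex), length = lens),
                              cds_start = 1L, label = "toy")
    skip <- sample(2:n_ex, 1)
    iso <- build_isoform(model, skip)
    keep <- setdiff(seq_len(n_ex), skip)
    cum <- cumsum(c(0, lens[keep]))
    for (k in seq_along(keep))
      expect_equal(map_coding_position(iso, keep[k]), cum[k] + 1L)
    ## downstream exons shift by exactly the skipped length
    for (e in keep[keep > skip])
      expect_equal(map_coding_position(model, e) -
                     map_coding_position(iso, e), lens[skip])
  }
})

test_that("intronic insertions are named in the printed order and in HGVS order", {
  gm <- gen_gene_model()
  expect_equal(name_intronic_insertion(gm$fl, 5, 15, 238),
               "c.1758-15_1758-16ins238")
  expect_equal(name_intronic_insertion(gm$sh, 5, 15, 238),
               "c.1590-15_1590-16ins238")
  expect_equal(name_intronic_insertion(gm$fl, 5, 15, 238, strict_hgvs = TRUE),
               "c.1758-16_1758-15ins238")
  expect_equal(name_intronic_insertion(gm$fl, 2, 1, 1), "c.490-1_490-2ins1")
})

test_that("translation stops at the first stop and matches an independent oracle", {
  toy <- transcript_model(data.frame(id = 1, length = 9L), 1L, "t",
                          "ATGAAATAA")
  tr <- translate_and_scan(toy)
  expect_equal(tr$protein_length, 2L)
  expect_equal(tr$stop_codon, 3L)
  expect_equal(tr$protein, "MK")
  set.seed(82)
  for (r in 1:30) {
    len <- 3 * sample(20:200, 1)
    dna <- rand_dna_test(len)
    model <- transcript_model(data.frame(id = 1, length = len), 1L, "t", dna)
    got <- translate_and_scan(model)
    want <- oracle_translate(dna)
    expect_equal(got$protein, toupper(want$protein))
    if (is.na(want$stop)) expect_true(got$nonstop)
    else expect_equal(got$stop_codon, want$stop)
  }
})

test_that("isoform comparison quantifies frameshift, aberrant tail and loss", {
  gm <- gen_gene_model()
  same <- compare_isoforms(gm$fl, gm$fl)
  expect_false(same$frameshift)
  expect_equal(same$aberrant_aa, 0L)
  expect_equal(same$aa_lost, 0L)
  expect_false(same$ptc)

  in_frame <- compare_isoforms(gm$fl, gm$sh)
  expect_false(in_frame$frameshift)          # 168 nt is a codon multiple
  expect_equal(in_frame$aa_lost, 56L)

  skip5 <- compare_isoforms(gm$fl, build_isoform(gm$fl, 5))
  expect_true(skip5$frameshift)              # 100 mod 3 = 1
  expect_true(skip5$ptc)
  expect_gt(skip5$aberrant_aa, 0L)
  expect_false(skip5$nmd_candidate)          # stop lands in the final exon

  ## brute-force translate-and-diff oracle
  mut <- build_isoform(gm$fl, 5)
  wt_p <- oracle_translate(gm$fl$sequence)$protein
  mut_p <- oracle_translate(mut$sequence)$protein
  lcp <- 0
  while (lcp < min(nchar(wt_p), nchar(mut_p)) &&
         substr(wt_p, lcp + 1, lcp + 1) == substr(mut_p, lcp + 1, lcp + 1))
    lcp <- lcp + 1
  expect_equal(skip5$aberrant_aa, nchar(mut_p) - lcp)
  expect_equal(skip5$truncated_protein_length, nchar(mut_p))
  expect_equal(skip5$aa_lost, nchar(wt_p) - nchar(mut_p))
})

test_that("exon-skip frameshift follows the mod-3 rule on random models", {
  set.seed(83)
  for (r in 1:30) {
    n_ex <- sample(3:6, 1)
    lens <- sample(30:200, n_ex, replace = TRUE)
    dna <- paste0("ATG", rand_dna_test(sum(lens) - 3))
    model <- transcript_model(data.frame(id = seq_len(n_ex), length = lens),
                              1L, "t", dna)
    skip <- sample(2:n_ex, 1)
    rep <- compare_isoforms(model, build_isoform(model, skip))
    expect_equal(rep$frameshift, lens[skip] %% 3 != 0)
  }
})

test_that("in-silico RT-PCR reproduces the four printed amplicons", {
  gm <- gen_gene_model()
  sizes <- vapply(list(gm$fl, build_isoform(gm$fl, 5), gm$sh,
                       build_isoform(gm$sh, 5)),
                  insilico_rtpcr, integer(1),
                  fwd = gm$primers$fwd, rev = gm$primers$rev)
  expect_equal(sizes, c(421L, 321L, 253L, 153L))
  ## amplicon differences equal the lengths of the distinguishing exons
  expect_equal(sizes[1] - sizes[2], gm$fl$exons$length[5])
  expect_equal(sizes[3] - sizes[4], gm$fl$exons$length[5])
  expect_equal(sizes[1] - sizes[3], gm$fl$exons$length[4])
  expect_equal(sizes[2] - sizes[4], gm$fl$exons$length[4])
  ## a missing primer exon yields no amplicon
  expect_true(is.na(insilico_rtpcr(build_isoform(gm$fl, 3), gm$primers$fwd,
                                   gm$primers$rev)))
  ## adjacent-exon amplicon, hand-computed
  toy <- transcript_model(data.frame(id = 1:2, length = c(100L, 80L)), 1L)
  expect_equal(insilico_rtpcr(toy, list(exon = 1, offset = 91L),
                              list(exon = 2, offset = 20L)), 30L)
  ## random placements equal coordinate arithmetic
  set.seed(84)
  for (r in 1:20) {
    lens <- sample(50:200, 4)
    m <- transcript_model(data.frame(id = 1:4, length = lens), 1L)
    f <- list(exon = 1, offset = sample(lens[1], 1))
    v <- list(exon = 4, offset = sample(lens[4], 1))
    expect_equal(insilico_rtpcr(m, f, v),
                 (sum(lens[1:3]) + v$offset) - f$offset + 1L)
  }
})

test_that("NMD candidacy follows the last-junction 50 nt rule", {
  m <- transcript_model(data.frame(id = 1:3, length = c(200L, 200L, 200L)),
                        1L)
  last_junction <- 400L
  expect_true(nmd_flag(m, last_junction - 200L))
  expect_false(nmd_flag(m, 450L))            # PTC in the final exon
  expect_false(nmd_flag(transcript_model(data.frame(id = 1, length = 300L),
                                         1L), 100L))
  set.seed(85)
  for (p in sample(1:600, 20))
    expect_equal(nmd_flag(m, p), (last_junction - p) > 50)
})
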