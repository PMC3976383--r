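test_that("poly(A) detection anchors at the 3' end and respects constraints", {
  pa <- find_polya(paste0(strrep("G", 20), strrep("A", 45)))
  expect_equal(pa$length, 45L)
  expect_equal(pa$start, 21L)
  expect_equal(find_polya(strrep("C", 50))$length, 0L)
  ## shorter than min_len -> empty
  expect_equal(find_polya(paste0(strrep("G", 20), "AAAA"), min_len = 10)$length,
               0L)
  ## interruptions counted; leading non-A bases are trimmed off the tract
  pa2 <- find_polya(paste0("GGGG", strrep("A", 20), "T", strrep("A", 10),
                           "T", strrep("A", 10)))
  expect_equal(pa2$interruptions, 2L)
  expect_equal(pa2$start, 5L)
  expect_equal(pa2$length, 42L)
})

test_that("poly(A) detection equals an exhaustive suffix-scan oracle", {
  set.seed(41)
  oracle <- function(s, min_len = 10, frac = 0.1) {
    b <- strsplit(s, "")[[1]]; n <- length(b)
    for (st in seq_len(n)) {
      w <- b[st:n]
      nonA <- w != "A"
      if (sum(nonA) / length(w) > frac) next
      if (length(w) > 1 && any(nonA[-1] & nonA[-length(w)])) next
      while (length(w) && w[1] != "A") {
        st <- st + 1; w <- w[-1]
      }
      if (length(w) < min_len) return(0L)
      return(c(start = st, len = length(w)))
    }
    0L
  }
  for (r in 1:200) {
    tail_len <- sample(5:40, 1)
    tail <- rep("A", tail_len)
    ints <- which(runif(tail_len) < 0.08)
    ints <- ints[ints > 1 & c(TRUE, diff(ints) > 1)]
    tail[ints] <- "T"
    s <- paste0(rand_dna_test(sample(10:40, 1)), paste(tail, collapse = ""))
    got <- find_polya(s)
    want <- oracle(s)
    if (identical(want, 0L)) expect_equal(got$length, 0L)
    else {
      expect_equal(got$start, unname(want["start"]))
      expect_equal(got$length, unname(want["len"]))
    }
    if (got$length > 0) {
      w <- strsplit(substr(s, got$start, got$end), "")[[1]]
      nonA <- w != "A"
      expect_false(any(nonA[-1] & nonA[-length(w)]))
    }
  }
})

test_that("dinucleotide repeat detection finds the 3'-most maximal run", {
  r <- find_dinucleotide_repeat(paste0(strrep("G", 10), strrep("CT", 8)))
  expect_equal(r$unit, "CT")
  expect_equal(r$copies, 8L)
  expect_equal(find_dinucleotide_repeat("GACGACGTT")$copies, 0L)
  ## homopolymers are not dinucleotide repeats
  expect_equal(find_dinucleotide_repeat(strrep("A", 20))$copies, 0L)
  ## planted (GA)k against a brute-force tandem scanner
  set.seed(42)
  brute <- function(s, min_copies = 3) {
    n <- nchar(s); best <- list(copies = 0L, end = 0L)
    for (st in seq_len(max(n - 1, 0))) {
      u <- substr(s, st, st + 1)
      if (substr(u, 1, 1) == substr(u, 2, 2)) next
      k <- 1
      while (st + 2 * k + 1 <= n && substr(s, st + 2 * k, st + 2 * k + 1) == u)
        k <- k + 1
      if (st >= 3 && substr(s, st - 2, st - 1) == u) next
      e <- st + 2 * k - 1
      if (k >= min_copies && (best$copies == 0 || e > best$end ||
                              (e == best$end && k > best$copies)))
        best <- list(unit = u, copies = k, start = st, end = e)
    }
    best
  }
  for (r in 1:100) {
    s <- paste0(rand_dna_test(sample(5:20, 1)),
                strrep("GA", sample(3:9, 1)),
                rand_dna_test(sample(0:6, 1)))
    got <- find_dinucleotide_repeat(s)
    want <- brute(s)
    expect_equal(got$copies, want$copies)
    if (want$copies > 0) {
      expect_equal(got$unit, want$unit)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("the default insert decomposes into the observed architecture", {
  ins <- gen_insert(seed = 5)
  expect_equal(nchar(ins), 132 + 16 + 45)
  d <- decompose_insert(ins, tsd = "ACGTACGTACGTAC")
  expect_equal(d$body$length, 132L)
  expect_equal(d$`repeat`$unit, "CT")
  expect_equal(d$`repeat`$copies, 8L)
  expect_equal(d$polya$length, 45L)
  expect_equal(d$tsd_length, 14L)
  expect_false(d$atypical)
})

test_that("degenerate inserts decompose sensibly", {
  d <- decompose_insert(strrep("A", 60))
  expect_equal(d$body$length, 0L)
  expect_equal(d$polya$length, 60L)
  expect_equal(d$`repeat`$copies, 0L)
  ## no poly(A) at all -> atypical, body-only
  d2 <- decompose_insert(strrep("G", 30))
  expect_true(d2$atypical)
  expect_equal(d2$body$length, 30L)
})

test_that("decomposition inverts the generator over random architectures", {
  set.seed(43)
  for (r in 1:100) {
    p <- list(body = sample(80:200, 1), copies = sample(3:12, 1),
              polya = sample(20:60, 1))
    ins <- gen_insert(p$body, p$copies, p$polya, seed = 5000 + r)
    d <- decompose_insert(ins)
    expect_equal(d$body$length, p$body)
    expect_equal(d$`repeat`$unit, "CT")
    expect_equal(d$`repeat`$copies, p$copies)
    expect_equal(d$polya$length, p$polya)
    ## conservation: components tile the insert
    expect_equal(d$body$length + 2L * d$`repeat`$copies + d$polya$length,
                 d$total_length)
  }
})

test_that("decomposition is idempotent on its own components", {
  ins <- gen_insert(seed = 6)
  d <- decompose_insert(ins)
  body <- substr(ins, d$body$start, d$body$end)
  again <- decompose_insert(paste0(body, strrep("CT", d$`repeat`$copies),
                                   substr(ins, d$polya$start, d$polya$end)))
  expect_equal(again$body$length, d$body$length)
  expect_equal(again$polya$length, d$polya$length)
})

test_that("decomposition exports valid GFF3 and JSON", {
  d <- decompose_insert(gen_insert(seed = 7), tsd = "TTTTAAAACCCCGG")
  g <- tempfile(fileext = ".gff3"); j <- tempfile(fileext = ".json")
  decomposition_to_gff(d, g)
  lines <- readLines(g)
  expect_equal(lines[1], "##gff-version 3")
  expect_length(grep("SINE_element", lines), 1)
  decomposition_to_json(d, j)
  back <- jsonlite::read_json(j)
  expect_equal(back$total_length, d$total_length)
  expect_equal(back$polya$length, d$polya$length)
})
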