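## Independent oracles and small fixture builders shared across tests.

## Build a genotype table from character genotype strings like "AA", "AB",
## "--" (missing); one string per sample x marker.
gt_from_strings <- function(status, geno, chrom = "chr1",
                            pos = NULL, kind = NULL) {
  n <- length(status)
  m <- ncol(geno)
  a1 <- matrix(substr(geno, 1, 1), n, m)
  a2 <- matrix(substr(geno, 2, 2), n, m)
  a1[a1 == "-"] <- NA; a2[a2 == "-"] <- NA
  samples <- data.frame(id = sprintf("S%02d", seq_len(n)), status = status,
                        stringsAsFactors = FALSE)
  markers <- data.frame(id = sprintf("m%03d", seq_len(m)), chrom = chrom,
                        pos = pos %||% seq(1000, by = 1000, length.out = m),
                        kind = kind %||% rep("SNP", m),
                        stringsAsFactors = FALSE)
  genotype_table(samples, markers, a1, a2)
}

## Random biallelic genotype table.
random_gt <- function(n_case, n_ctrl, n_carr = 0, m, miss = 0.05,
                      p = NULL) {
  status <- c(rep("case", n_case), rep("control", n_ctrl),
              rep("obligate_carrier", n_carr))
  n <- length(status)
  p <- p %||% runif(m, 0.2, 0.8)
  draw <- function() matrix(ifelse(runif(n * m) <
                                     rep(p, each = n), "A", "B"), n, m)
  a1 <- draw(); a2 <- draw()
  mm <- matrix(runif(n * m) < miss, n, m)
  a1[mm] <- NA; a2[mm] <- NA
  geno <- matrix(paste0(pmin(a1, a2), pmax(a1, a2)), n, m)
  geno[is.na(a1)] <- "--"
  gt_from_strings(status, geno)
}

## Exhaustive-interval oracle for the homozygosity scanner: enumerates all
## O(m^2) intervals, recomputes supporting sets and constraints directly,
## and keeps the maximal qualifying intervals. Returns a data.frame of
## marker-index bounds (i, j), sorted.
oracle_regions <- function(table, min_frac, tol) {
  st <- table$samples$status
  cases <- which(st == "case")
  ctrls <- which(st == "control")
  carrs <- which(st == "obligate_carrier")
  m <- ncol(table$a1)
  shared <- vapply(seq_len(m), function(jm) {
    a1 <- table$a1[cases, jm]; a2 <- table$a2[cases, jm]
    hom <- !is.na(a1) & a1 == a2
    if (!any(hom)) return(NA_character_)
    tab <- table(a1[hom])
    names(tab)[order(-tab, names(tab))][1]
  }, character(1))
  hom_sh <- function(i, jm) {
    !is.na(shared[jm]) && !is.na(table$a1[i, jm]) &&
      table$a1[i, jm] == shared[jm] && table$a2[i, jm] == shared[jm]
  }
  valid <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    for (j in i:m) {
      supp <- vapply(cases, function(s)
        sum(!vapply(i:j, function(jm) hom_sh(s, jm), logical(1))) <= tol,
        logical(1))
      if (sum(supp) / length(cases) < min_frac) next
      bad_ctrl <- any(vapply(ctrls, function(s)
        all(vapply(i:j, function(jm) hom_sh(s, jm), logical(1))),
        logical(1)))
      bad_carr <- any(vapply(carrs, function(s)
        all(vapply(i:j, function(jm) hom_sh(s, jm), logical(1))),
        logical(1)))
      valid[i, j] <- !bad_ctrl && !bad_carr
    }
  }
  out <- list()
  for (i in seq_len(m)) for (j in i:m) {
    if (!valid[i, j]) next
    contained <- FALSE
    for (i2 in seq_len(i)) for (j2 in j:m) {
      if ((i2 != i || j2 != j) && valid[i2, j2]) contained <- TRUE
    }
    if (!contained) out[[length(out) + 1]] <- c(i = i, j = j)
  }
  if (length(out) == 0)
    return(data.frame(i = integer(), j = integer()))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$i, df$j), ]
}

## Map scan_regions output back to marker-index bounds for comparison.
regions_to_indices <- function(regions, table) {
  if (nrow(regions) == 0) return(data.frame(i = integer(), j = integer()))
  df <- data.frame(
    i = match(regions$start_bp, table$markers$pos),
    j = match(regions$end_bp, table$markers$pos))
  df <- df[order(df$i, df$j), ]
  rownames(df) <- NULL
  df
}

## Independent translation oracle (seqinr's codon table, not the
## implementation's path).
oracle_translate <- function(dna) {
  aa <- seqinr::translate(strsplit(tolower(dna), "")[[1]])
  stop_at <- which(aa == "*")[1]
  if (is.na(stop_at)) list(protein = paste(aa, collapse = ""), stop = NA)
  else list(protein = paste(aa[seq_len(stop_at - 1)], collapse = ""),
            stop = stop_at)
}

## Minimal aligned-read row builder for hand-made read sets.
read_row <- function(sample, pos, end, lclip = 0, rclip = 0, lseq = "",
                     rseq = "", seq = "A") {
  data.frame(qname = paste0("q", pos, "_", sample, "_", runif(1)),
             sample = sample, pos = pos, end = end, lclip = lclip,
             rclip = rclip, lseq = lseq, rseq = rseq, seq = seq,
             stringsAsFactors = FALSE)
}

subset_markers_for_test <- function(tab, j) {
  genotype_table(tab$samples, tab$markers[j, , drop = FALSE],
                 tab$a1[, j, drop = FALSE], tab$a2[, j, drop = FALSE])
}

rand_dna_test <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
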