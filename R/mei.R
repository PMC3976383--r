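#' Construct an aligned-read table
#'
#' Minimal alignment representation used by the insertion caller: one row per
#' mapped read with its aligned reference interval and any soft-clipped
#' prefix/suffix. Only the fields the caller consumes are kept (a real-BAM
#' adapter would populate the same columns).
#'
#' @param df data.frame with columns `qname`, `sample`, `pos` (1-based start
#'   of the aligned portion), `end` (last aligned base), `lclip`, `rclip`
#'   (soft-clip lengths), `lseq`, `rseq` (clipped sequences) and `seq`.
#' @return data.frame of class `aligned_reads`.
#' @export
aligned_reads <- function(df) {
  need <- c("qname", "sample", "pos", "end", "lclip", "rclip",
            "lseq", "rseq", "seq")
  if (!all(need %in% names(df))) stopf("aligned_reads needs columns %s",
                                       paste(need, collapse = ", "))
  stopifnot(all(df$lclip >= 0), all(df$rclip >= 0), all(df$end >= df$pos))
  class(df) <- c("aligned_reads", "data.frame")
  df
}

#' Read a SAM-subset text file
#'
#' Parses the plain-text SAM dialect the pipeline exchanges: header lines
#' starting with `@` are skipped; of each alignment line the fields QNAME,
#' POS, CIGAR and SEQ are used, with CIGAR restricted to the
#' `[nS] nM [nS]` shape. The sample is taken from an `RG:Z:` tag when
#' present, else from the `sample` argument.
#'
#' @param path SAM file path.
#' @param sample fallback sample id.
#' @return an [aligned_reads()] table.
#' @export
read_sam <- function(path, sample = "sample1") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stopf("malformed SAM line (%d fields)", length(f))
    ops <- regmatches(f[6], gregexpr("[0-9]+[A-Z]", f[6]))[[1]]
    lens <- as.integer(sub("[A-Z]", "", ops))
    kinds <- sub("[0-9]+", "", ops)
    if (!all(kinds %in% c("S", "M")) || sum(kinds == "M") != 1)
      stopf("unsupported CIGAR: %s", f[6])
    lclip <- if (kinds[1] == "S") lens[1] else 0L
    rclip <- if (kinds[length(kinds)] == "S" && length(kinds) > 1)
      lens[length(kinds)] else 0L
    mlen <- lens[kinds == "M"]
    rg <- grep("^RG:Z:", f[-(1:11)], value = TRUE)
    data.frame(qname = f[1],
               sample = if (length(rg)) sub("^RG:Z:", "", rg[1]) else sample,
               pos = as.integer(f[4]), end = as.integer(f[4]) + mlen - 1L,
               lclip = lclip, rclip = rclip,
               lseq = substr(f[10], 1L, lclip),
               rseq = substr(f[10], lclip + mlen + 1L, nchar(f[10])),
               seq = f[10], stringsAsFactors = FALSE)
  })
  aligned_reads(do.call(rbind, rows))
}

#' Write aligned reads as SAM-subset text
#' @param reads an [aligned_reads()] table.
#' @param path output path.
#' @param rname reference sequence name.
#' @param ref_len reference length for the `@SQ` header.
#' @return invisibly, the path.
#' @export
write_sam <- function(reads, path, rname = "ref", ref_len = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:coordinate"
  if (!is.null(ref_len))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", rname, ref_len))
  o <- order(reads$pos)
  body <- vapply(o, function(i) {
    r <- reads[i, ]
    cigar <- paste0(if (r$lclip > 0) sprintf("%dS", r$lclip) else "",
                    sprintf("%dM", r$end - r$pos + 1L),
                    if (r$rclip > 0) sprintf("%dS", r$rclip) else "")
    paste(r$qname, 0L, rname, r$pos, 60L, cigar, "*", 0L, 0L, r$seq, "*",
          sprintf("RG:Z:%s", r$sample), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Cluster soft-clip breakpoints
#'
#' Groups right-clip positions (last aligned base of reads clipped on the
#' right) and left-clip positions (first aligned base of reads clipped on
#' the left) into clusters of nearby positions; adjacent positions no more
#' than `cluster_window` apart join the same cluster. Each cluster records
#' its modal breakpoint (ties broken toward the smaller position) and the
#' member clipped sequences.
#'
#' @param reads an [aligned_reads()] table.
#' @param min_clip minimum soft-clip length to count as evidence (default 8).
#' @param cluster_window maximum gap between member positions (default 5).
#' @return list with elements `right` and `left`; each a list of clusters
#'   `list(breakpoint, positions, seqs, n)`.
#' @export
collect_clip_clusters <- function(reads, min_clip = 8, cluster_window = 5) {
  one_side <- function(pos, seqs) {
    if (length(pos) == 0) return(list())
    o <- order(pos)
    pos <- pos[o]; seqs <- seqs[o]
    grp <- cumsum(c(1, diff(pos) > cluster_window))
    lapply(split(seq_along(pos), grp), function(idx) {
      p <- pos[idx]
      tab <- table(p)
      list(breakpoint = as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1]),
           positions = p, seqs = seqs[idx], n = length(idx))
    })
  }
  r <- reads$rclip >= min_clip
  l <- reads$lclip >= min_clip
  list(right = unname(one_side(reads$end[r], reads$rseq[r])),
       left = unname(one_side(reads$pos[l], reads$lseq[l])))
}

#' Pair clip clusters into insertion calls
#'
#' A right-clip cluster at reference position R is paired with a left-clip
#' cluster at L when `tsd_min <= R - L + 1 <= tsd_max`: reads clipped on
#' both sides of a target-site duplication terminate at its two copies, so
#' the interval `[L..R]` is the duplicated motif. Ambiguous pairings are
#' resolved by closest distance; exact ties are all reported with
#' `ambiguous = TRUE`.
#'
#' @param clusters output of [collect_clip_clusters()].
#' @param tsd_min,tsd_max admissible TSD length bounds (defaults 4 and 30).
#' @param reference reference sequence (character) covering the cluster
#'   positions; the TSD sequence is read from it.
#' @return list of ungenotyped insertion calls: `list(l, r, tsd_length,
#'   tsd_sequence, right_cluster, left_cluster, ambiguous)`.
#' @export
pair_breakpoints <- function(clusters, tsd_min = 4, tsd_max = 30, reference) {
  calls <- list()
  used <- function(cl) vapply(cl, function(x) x$breakpoint, integer(1))
  rb <- used(clusters$right); lb <- used(clusters$left)
  if (length(rb) == 0 || length(lb) == 0) return(calls)
  for (i in seq_along(rb)) {
    tsd_len <- rb[i] - lb + 1L
    ok <- which(tsd_len >= tsd_min & tsd_len <= tsd_max)
    if (length(ok) == 0) next
    best <- ok[which(tsd_len[ok] == min(tsd_len[ok]))]
    for (j in best) {
      l <- lb[j]; r <- rb[i]
      calls[[length(calls) + 1]] <- list(
        l = l, r = r, tsd_length = r - l + 1L,
        tsd_sequence = substr(reference, l, r),
        right_cluster = clusters$right[[i]], left_cluster = clusters$left[[j]],
        ambiguous = length(best) > 1)
    }
  }
  calls
}

## Majority consensus of clipped tails; `from_right` aligns sequences on
## their 3' ends (for left-clipped insert suffixes).
clip_consensus <- function(seqs, min_agreement = 0.6, max_len = Inf,
                           from_right = FALSE) {
  if (length(seqs) == 0) return(list(seq = "", low_confidence = TRUE))
  if (length(seqs) == 1)
    return(list(seq = substr(seqs, 1, min(nchar(seqs), max_len)),
                low_confidence = TRUE))
  if (from_right) {
    rev_str <- function(s) vapply(strsplit(s, ""), function(x)
      paste(rev(x), collapse = ""), character(1))
    out <- clip_consensus(rev_str(seqs), min_agreement, max_len)
    return(list(seq = vapply(list(out$seq), function(s)
      paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1)),
      low_confidence = out$low_confidence))
  }
  maxc <- min(max(nchar(seqs)), max_len)
  cons <- character(0)
  for (cpos in seq_len(maxc)) {
    b <- substr(seqs[nchar(seqs) >= cpos], cpos, cpos)
    if (length(b) == 0) break
    tab <- table(b)
    top <- names(tab)[order(-tab, names(tab))][1]
    if (tab[[top]] / length(b) < min_agreement) break
    cons <- c(cons, top)
  }
  list(seq = paste(cons, collapse = ""), low_confidence = FALSE)
}

#' Reconstruct partial insert ends from clipped tails
#'
#' Per-column majority consensus of the right-clipped tails (the 5' end of
#' the insert) and of the left-clipped tails aligned on their 3' ends (the
#' 3' end of the insert), truncated at the first column whose majority base
#' falls below `min_agreement` support. With reads shorter than the insert
#' only these partial ends are recoverable; each consensus is at most
#' `read_length - min_clip` bases.
#'
#' @param call an insertion call from [pair_breakpoints()].
#' @param min_agreement minimum per-column agreement fraction (default 0.6).
#' @param read_length read length (default 51).
#' @param min_clip minimum clip used in clustering (default 8).
#' @return the call with `insert_end_5p`, `insert_end_3p` and
#'   `low_confidence` fields added.
#' @export
reconstruct_insert_ends <- function(call, min_agreement = 0.6,
                                    read_length = 51, min_clip = 8) {
  cap <- read_length - min_clip
  c5 <- clip_consensus(call$right_cluster$seqs, min_agreement, cap)
  c3 <- clip_consensus(call$left_cluster$seqs, min_agreement, cap,
                       from_right = TRUE)
  call$insert_end_5p <- c5$seq
  call$insert_end_3p <- c3$seq
  call$low_confidence <- c5$low_confidence || c3$low_confidence
  call
}

#' Genotype an insertion call from read support
#'
#' Supporting reads are those soft-clipped (>= `min_clip`) at either
#' breakpoint (within `cluster_window`); each attests the insertion at one
#' junction. A spanning read — fully crossing the duplicated motif `[L..R]`
#' unclipped — attests the reference allele at both junctions and therefore
#' contributes two reference observations. The insertion allele fraction is
#' `vaf = supporting / (supporting + 2 * spanning)`, which estimates the
#' fraction of molecules carrying the insertion: about 1 in a homozygote,
#' 0.5 in a carrier, 0 in a homozygous-wildtype sample. Genotype per sample
#' by thresholds; zero coverage gives `no_call` with a `zero_coverage` flag.
#'
#' @param call an insertion call from [pair_breakpoints()].
#' @param reads an [aligned_reads()] table (all samples).
#' @param min_clip,cluster_window as in [collect_clip_clusters()].
#' @param thresholds named list: `hom_ins` (default 0.85), `het_lo` (0.25),
#'   `het_hi` (0.75), `hom_ref` (0.10).
#' @return the call with a `genotypes` data.frame added: per sample
#'   `supporting_reads`, `ref_obs`, `spanning_reads`, `vaf`, `genotype`,
#'   `zero_coverage`.
#' @export
genotype_insertion <- function(call, reads, min_clip = 8, cluster_window = 5,
                               thresholds = list(hom_ins = 0.85,
                                                 het_lo = 0.25, het_hi = 0.75,
                                                 hom_ref = 0.10)) {
  L <- call$l; R <- call$r
  sup_right <- reads$rclip >= min_clip & abs(reads$end - R) <= cluster_window
  sup_left <- reads$lclip >= min_clip & abs(reads$pos - L) <= cluster_window
  supporting <- sup_right | sup_left
  spanning <- reads$pos <= L - 1 & reads$end >= R + 1 &
    reads$lclip < min_clip & reads$rclip < min_clip
  per <- lapply(split(seq_len(nrow(reads)), reads$sample), function(idx) {
    s <- sum(supporting[idx])
    ro <- 2L * sum(spanning[idx])
    tot <- s + ro
    vaf <- if (tot > 0) s / tot else NA_real_
    gt <- if (tot == 0) "no_call"
    else if (vaf >= thresholds$hom_ins) "hom_ins"
    else if (vaf >= thresholds$het_lo && vaf <= thresholds$het_hi) "het"
    else if (vaf <= thresholds$hom_ref) "hom_ref"
    else "no_call"
    data.frame(supporting_reads = s, ref_obs = ro,
               spanning_reads = sum(spanning[idx]), vaf = vaf, genotype = gt,
               zero_coverage = tot == 0, stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, per)
  g <- cbind(sample = names(per), g)
  rownames(g) <- NULL
  call$genotypes <- g
  call
}

#' Call and genotype insertions from aligned reads
#'
#' End-to-end split-read insertion discovery: clip clustering, breakpoint
#' pairing with TSD inference, partial insert-end reconstruction and
#' per-sample read-support genotyping.
#'
#' @param reads an [aligned_reads()] table.
#' @param reference reference sequence (character string).
#' @param min_clip,cluster_window,tsd_min,tsd_max,min_agreement,read_length
#'   detection parameters; see the stage functions.
#' @return list of genotyped insertion calls.
#' @export
call_insertions <- function(reads, reference, min_clip = 8,
                            cluster_window = 5, tsd_min = 4, tsd_max = 30,
                            min_agreement = 0.6, read_length = 51) {
  clusters <- collect_clip_clusters(reads, min_clip, cluster_window)
  calls <- pair_breakpoints(clusters, tsd_min, tsd_max, reference)
  lapply(calls, function(cl) {
    cl <- reconstruct_insert_ends(cl, min_agreement, read_length, min_clip)
    genotype_insertion(cl, reads, min_clip, cluster_window)
  })
}

#' Read-depth ratio over the duplicated motif
#'
#' Mean per-base aligned depth over the TSD interval `[L..R]` divided by the
#' mean depth over flanking windows. In a sample homozygous for the
#' insertion both TSD copies map onto the single reference copy, so the
#' ratio is about 2 — the sudden read-depth step characteristic of a
#' duplication.
#'
#' @param reads an [aligned_reads()] table (one sample's reads).
#' @param call an insertion call.
#' @param flank flank width in bp (default 200).
#' @return depth ratio (TSD / flank).
#' @export
tsd_depth_ratio <- function(reads, call, flank = 200) {
  depth_at <- function(p) sum(reads$pos <= p & reads$end >= p)
  tsd_pos <- call$l:call$r
  fl <- c(max(1, call$l - flank):(call$l - 1 - 10),
          (call$r + 1 + 10):(call$r + flank))
  mean(vapply(tsd_pos, depth_at, numeric(1))) /
    mean(vapply(fl, depth_at, numeric(1)))
}

#' Write insertion calls as symbolic VCF records
#'
#' Emits one `<INS>` record per call with INFO keys `TSDLEN`, `TSDSEQ`,
#' `END5P`, `END3P` and per-sample `GT:AD` (AD = reference observations,
#' supporting reads).
#'
#' @param calls list of genotyped insertion calls.
#' @param path output path.
#' @param chrom chromosome name for the records.
#' @param reference reference sequence (for the REF base at L-1).
#' @return invisibly, the path.
#' @export
write_mei_vcf <- function(calls, path, chrom = "chr10", reference) {
  hdr <- c("##fileformat=VCFv4.2",
           "##ALT=<ID=INS,Description=\"Insertion\">",
           "##INFO=<ID=TSDLEN,Number=1,Type=Integer,Description=\"Target site duplication length\">",
           "##INFO=<ID=TSDSEQ,Number=1,Type=String,Description=\"Target site duplication sequence\">",
           "##INFO=<ID=END5P,Number=1,Type=String,Description=\"Partial insert 5prime end\">",
           "##INFO=<ID=END3P,Number=1,Type=String,Description=\"Partial insert 3prime end\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=2,Type=Integer,Description=\"Reference observations, supporting reads\">")
  samples <- if (length(calls)) calls[[1]]$genotypes$sample else character(0)
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))
  gt_map <- c(hom_ins = "1/1", het = "0/1", hom_ref = "0/0", no_call = "./.")
  body <- vapply(calls, function(cl) {
    info <- sprintf("TSDLEN=%d;TSDSEQ=%s;END5P=%s;END3P=%s", cl$tsd_length,
                    cl$tsd_sequence,
                    ifelse(nzchar(cl$insert_end_5p %||% ""), cl$insert_end_5p, "."),
                    ifelse(nzchar(cl$insert_end_3p %||% ""), cl$insert_end_3p, "."))
    g <- cl$genotypes
    fmt <- sprintf("%s:%d,%d", gt_map[g$genotype], g$ref_obs,
                   g$supporting_reads)
    paste(c(chrom, cl$l - 1L, ".", substr(reference, cl$l - 1L, cl$l - 1L),
            "<INS>", ".", "PASS", info, "GT:AD", fmt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
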