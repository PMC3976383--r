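#' Locate a 3'-anchored interrupted poly(A) tract
#'
#' Finds the longest suffix of the sequence whose adenine fraction is at
#' least `1 - max_interrupt_frac` and which never contains two adjacent
#' non-A bases; leading non-A bases are trimmed so the tract starts on an A
#' (poly(A) tails are occasionally interrupted by single pyrimidines, T in
#' the observed allele). Returns an empty interval when the best tract is
#' shorter than `min_len`.
#'
#' @param seq DNA sequence (character string).
#' @param min_len minimum tract length (default 10).
#' @param max_interrupt_frac maximum non-A fraction (default 0.1).
#' @return list `start`, `end` (1-based, inclusive; both 0 when absent),
#'   `length`, `interruptions`.
#' @export
find_polya <- function(seq, min_len = 10, max_interrupt_frac = 0.1) {
  b <- strsplit(toupper(seq), "")[[1]]
  n <- length(b)
  empty <- list(start = 0L, end = 0L, length = 0L, interruptions = 0L)
  if (n == 0) return(empty)
  nonA <- b != "A"
  ## suffix [s..n]: non-A count and adjacency from cumulative scans
  nonA_tail <- rev(cumsum(rev(nonA)))
  adj <- c(nonA[-n] & nonA[-1], FALSE)      # adj[i]: i and i+1 both non-A
  adj_tail <- rev(cumsum(rev(as.numeric(adj))))
  best <- 0L
  for (s in seq_len(n)) {
    len <- n - s + 1L
    if (nonA_tail[s] / len > max_interrupt_frac) next
    if (adj_tail[s] > 0) next
    best <- s
    break
  }
  if (best == 0L) return(empty)
  while (best <= n && b[best] != "A") best <- best + 1L
  len <- n - best + 1L
  if (len < min_len) return(empty)
  list(start = best, end = n, length = len,
       interruptions = as.integer(nonA_tail[best]))
}

#' Locate the dinucleotide repeat 5' of the poly(A)
#'
#' Finds the maximal tandem run of any 2-mer unit with at least `min_copies`
#' copies inside the search region, preferring the run nearest the 3' end
#' (i.e. nearest the poly(A) it linkers into). Returns zero copies when no
#' qualifying run exists.
#'
#' @param seq search region (the segment 5'-adjacent to the poly(A)).
#' @param min_copies minimum tandem copies (default 3).
#' @return list `unit`, `copies`, `start`, `end` (1-based within `seq`).
#' @export
find_dinucleotide_repeat <- function(seq, min_copies = 3) {
  b <- toupper(seq)
  n <- nchar(b)
  none <- list(unit = NA_character_, copies = 0L, start = 0L, end = 0L)
  if (n < 2 * min_copies) return(none)
  best <- none
  for (s in seq_len(n - 1)) {
    unit <- substr(b, s, s + 1)
    if (substr(unit, 1, 1) == substr(unit, 2, 2)) next  # homopolymer, not a dinucleotide motif
    k <- 1L
    while (s + 2 * k + 1 <= n &&
           substr(b, s + 2 * k, s + 2 * k + 1) == unit) k <- k + 1L
    if (k >= min_copies) {
      e <- s + 2L * k - 1L
      ## maximal run only (not a shifted sub-run), then prefer 3'-most end
      sub_run <- s >= 3 && substr(b, s - 2, s - 1) == unit
      if (!sub_run && (best$copies == 0L || e > best$end ||
                       (e == best$end && k > best$copies)))
        best <- list(unit = unit, copies = k, start = s, end = e)
    }
  }
  best
}

#' Decompose a resolved insert into its structural parts
#'
#' Parses a fully resolved retrotransposon insert 5' to 3' as: SINE body,
#' dinucleotide linker repeat, interrupted poly(A) tract — the canonical
#' tRNA-derived SINE architecture. The poly(A) is located first (3'
#' anchored), the dinucleotide repeat immediately 5' of it, and the body is
#' the 5' remainder. Component intervals are non-overlapping and, together
#' with an optional `unresolved` gap between repeat and poly(A), tile the
#' insert. The flanking target-site duplication is genomic, not part of the
#' insert, and is carried through for reporting.
#'
#' @param insert resolved insert sequence.
#' @param tsd target-site duplication sequence (reported, not parsed).
#' @param min_polya,max_interrupt_frac,min_copies detection thresholds
#'   (defaults 10, 0.1, 3).
#' @return list of class `sine_decomposition`: `total_length`, `tsd`,
#'   `tsd_length`, `body` (start/end/length), `repeat` (unit/copies/
#'   start/end), `polya` (start/end/length/interruptions), `unresolved`
#'   (NULL or start/end), `atypical`.
#' @export
decompose_insert <- function(insert, tsd = "", min_polya = 10,
                             max_interrupt_frac = 0.1, min_copies = 3) {
  insert <- toupper(insert)
  n <- nchar(insert)
  pa <- find_polya(insert, min_polya, max_interrupt_frac)
  atypical <- pa$length == 0L
  region_end <- if (pa$length > 0) pa$start - 1L else n
  rp <- if (region_end >= 2)
    find_dinucleotide_repeat(substr(insert, 1, region_end), min_copies)
  else list(unit = NA_character_, copies = 0L, start = 0L, end = 0L)
  body_end <- if (rp$copies > 0) rp$start - 1L else region_end
  unresolved <- NULL
  if (rp$copies > 0 && rp$end < region_end)
    unresolved <- list(start = rp$end + 1L, end = region_end)
  structure(list(
    total_length = n,
    tsd = tsd, tsd_length = nchar(tsd),
    body = list(start = if (body_end >= 1) 1L else 0L, end = body_end,
                length = max(body_end, 0L)),
    `repeat` = rp,
    polya = pa,
    unresolved = unresolved,
    atypical = atypical), class = "sine_decomposition")
}

#' @method print sine_decomposition
#' @export
print.sine_decomposition <- function(x, ...) {
  cat(sprintf("sine_decomposition: %d bp insert (TSD %d bp%s)\n",
              x$total_length, x$tsd_length,
              if (x$atypical) ", atypical" else ""))
  cat(sprintf("  body   %4d bp [%d..%d]\n", x$body$length, x$body$start,
              x$body$end))
  if (x$`repeat`$copies > 0)
    cat(sprintf("  repeat (%s)%d [%d..%d]\n", x$`repeat`$unit,
                x$`repeat`$copies, x$`repeat`$start, x$`repeat`$end))
  if (x$polya$length > 0)
    cat(sprintf("  polyA  %4d bp [%d..%d], %d interruption(s)\n",
                x$polya$length, x$polya$start, x$polya$end,
                x$polya$interruptions))
  invisible(x)
}

#' Export a decomposition as GFF3 sub-features
#' @param dec a `sine_decomposition`.
#' @param path output GFF3 path.
#' @param seqid feature sequence id (default "insert").
#' @return invisibly, the path.
#' @export
decomposition_to_gff <- function(dec, path, seqid = "insert") {
  rows <- character(0)
  add <- function(type, s, e, attr) {
    if (s >= 1 && e >= s)
      rows <<- c(rows, paste(seqid, "sinemap", type, s, e, ".", "+", ".",
                             attr, sep = "\t"))
  }
  add("mobile_genetic_element", 1, dec$total_length,
      sprintf("ID=ins;tsd=%s", dec$tsd))
  add("SINE_element", dec$body$start, dec$body$end, "ID=body;Parent=ins")
  if (dec$`repeat`$copies > 0)
    add("dinucleotide_repeat_microsatellite_feature", dec$`repeat`$start,
        dec$`repeat`$end, sprintf("ID=linker;Parent=ins;unit=%s;copies=%d",
                                  dec$`repeat`$unit, dec$`repeat`$copies))
  if (dec$polya$length > 0)
    add("polyA_sequence", dec$polya$start, dec$polya$end,
        sprintf("ID=polya;Parent=ins;interruptions=%d",
                dec$polya$interruptions))
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' JSON report for a decomposition
#' @param dec a `sine_decomposition`.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
decomposition_to_json <- function(dec, path) {
  jsonlite::write_json(unclass(dec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
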