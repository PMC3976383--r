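#' Construct a transcript model
#'
#' An exon-resolved transcript: ordered exons with lengths (optionally
#' genomic coordinates in `gstart`/`gend`), the transcript offset of the
#' first coding base, an isoform label and optionally the spliced transcript
#' sequence (whose length must equal the exon-length sum).
#'
#' @param exons data.frame with columns `id` and `length` (nt, >= 1);
#'   optional `gstart`, `gend` genomic columns.
#' @param cds_start 1-based transcript offset of the translation start.
#' @param label isoform label.
#' @param sequence optional spliced transcript sequence.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(exons, cds_start = 1L, label = "tx",
                             sequence = NULL) {
  stopifnot(is.data.frame(exons), all(exons$length >= 1))
  total <- sum(exons$length)
  if (cds_start < 1 || cds_start > total)
    stopf("cds_start %d outside transcript (length %d)", cds_start, total)
  if (!is.null(sequence) && nchar(sequence) != total)
    stopf("sequence length %d != exon sum %d", nchar(sequence), total)
  structure(list(exons = exons, cds_start = as.integer(cds_start),
                 label = label, sequence = sequence),
            class = "transcript_model")
}

#' @method print transcript_model
#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model '%s': %d exons, %d nt (CDS from %d)\n",
              x$label, nrow(x$exons), sum(x$exons$length), x$cds_start))
  invisible(x)
}

exon_cumstart <- function(model) {
  len <- model$exons$length
  stats::setNames(cumsum(c(0L, len[-length(len)])) + 1L,
                  as.character(model$exons$id))
}

#' Build an isoform by skipping exons
#'
#' Removes the named exons and remaps coding coordinates: a skipped exon 5'
#' of the translation start shifts `cds_start` left by its length; skipping
#' the exon containing the translation start is unsupported. The spliced
#' sequence, when present, is cut accordingly. Deterministic.
#'
#' @param model a [transcript_model()].
#' @param skip vector of exon ids to remove.
#' @return the derived `transcript_model` (label suffixed `-<id>` per
#'   skipped exon).
#' @export
build_isoform <- function(model, skip = NULL) {
  if (length(skip) == 0) return(model)
  ids <- as.character(model$exons$id)
  if (!all(as.character(skip) %in% ids))
    stopf("unknown exon id(s): %s",
          paste(setdiff(as.character(skip), ids), collapse = ", "))
  starts <- exon_cumstart(model)
  cds <- model$cds_start
  seq <- model$sequence
  keep_mask <- !ids %in% as.character(skip)
  for (sid in as.character(skip)) {
    s <- starts[sid]; len <- model$exons$length[ids == sid]
    if (cds >= s && cds < s + len)
      stopf("skipping exon %s would remove the translation start", sid)
    if (s + len <= cds) cds <- cds - len
  }
  if (!is.null(seq)) {
    pieces <- substring(seq, starts, starts + model$exons$length - 1L)
    seq <- paste(pieces[keep_mask], collapse = "")
  }
  transcript_model(model$exons[keep_mask, , drop = FALSE], cds,
                   paste0(model$label,
                          paste0("-", as.character(skip), collapse = "")),
                   seq)
}

#' Coding coordinate of an exon's first base
#'
#' 1-based coding (c.) position of the first base of the given exon;
#' intronic positions upstream of that acceptor are conventionally written
#' `{c.}-{n}`.
#'
#' @param model a [transcript_model()].
#' @param exon_id exon identifier.
#' @return integer c. position.
#' @export
map_coding_position <- function(model, exon_id) {
  starts <- exon_cumstart(model)
  key <- as.character(exon_id)
  if (!key %in% names(starts)) stopf("exon %s not in model", key)
  pos <- unname(starts[key]) - model$cds_start + 1L
  if (pos < 1) stopf("exon %s starts upstream of the coding sequence", key)
  pos
}

#' Name an intronic insertion in coding notation
#'
#' Builds the `c.{acc}-{o}_{acc}-{o+1}ins{len}` string for an insertion
#' between `o` and `o+1` nt upstream of an exon's acceptor, in the printed
#' descending order; `strict_hgvs = TRUE` emits the 5'-to-3' normalized
#' order `c.{acc}-{o+1}_{acc}-{o}ins{len}` instead.
#'
#' @param model a [transcript_model()].
#' @param exon_id exon whose acceptor the insertion precedes.
#' @param upstream_offset nt upstream of the acceptor (>= 1).
#' @param ins_len inserted length (bp).
#' @param strict_hgvs normalize the order (default FALSE).
#' @return variant name string.
#' @export
name_intronic_insertion <- function(model, exon_id, upstream_offset, ins_len,
                                    strict_hgvs = FALSE) {
  stopifnot(upstream_offset >= 1)
  acc <- map_coding_position(model, exon_id)
  o <- upstream_offset
  if (strict_hgvs)
    sprintf("c.%d-%d_%d-%dins%d", acc, o + 1L, acc, o, ins_len)
  else
    sprintf("c.%d-%d_%d-%dins%d", acc, o, acc, o + 1L, ins_len)
}

#' Translate a transcript and scan for the stop
#'
#' Standard-code translation from `cds_start` to the first stop codon.
#'
#' @param model a [transcript_model()] carrying its sequence.
#' @return list `protein_length` (aa before the stop), `stop_codon` (codon
#'   index of the stop; NA when none), `ptc_transcript_pos` (transcript
#'   position of the stop codon's first base), `nonstop` (no in-frame stop
#'   before the transcript end), `protein` (aa string).
#' @export
translate_and_scan <- function(model) {
  if (is.null(model$sequence)) stopf("model carries no sequence")
  cds <- substr(model$sequence, model$cds_start, nchar(model$sequence))
  n_codon <- nchar(cds) %/% 3
  if (n_codon == 0) stopf("no complete codon downstream of cds_start")
  codons <- substring(cds, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_idx <- which(aa == "*")[1]
  if (is.na(stop_idx)) {
    list(protein_length = n_codon, stop_codon = NA_integer_,
         ptc_transcript_pos = NA_integer_, nonstop = TRUE,
         protein = paste(aa, collapse = ""))
  } else {
    list(protein_length = stop_idx - 1L, stop_codon = stop_idx,
         ptc_transcript_pos = model$cds_start + 3L * (stop_idx - 1L),
         nonstop = FALSE,
         protein = paste(aa[seq_len(stop_idx - 1L)], collapse = ""))
  }
}

#' Compare a mutant isoform against wildtype
#'
#' Reports the reading-frame consequence of the exons missing from the
#' mutant: frameshift (skipped length not a multiple of 3), the aberrant
#' residues the mutant carries after the last residue shared with wildtype,
#' the truncated protein length, the residues lost (wildtype length minus
#' mutant length, the aberrant tail counting toward mutant length), the
#' premature-stop transcript position and whether the transcript is a
#' nonsense-mediated-decay candidate under the last-junction rule.
#'
#' @param wt,mut [transcript_model()]s with sequences, sharing `cds_start`
#'   ancestry (the mutant derived from wildtype via [build_isoform()]).
#' @param boundary_rule NMD last-junction distance in nt (default 50).
#' @return list of class `consequence_report`.
#' @export
compare_isoforms <- function(wt, mut, boundary_rule = 50) {
  wt_ids <- as.character(wt$exons$id)
  mut_ids <- as.character(mut$exons$id)
  skipped <- setdiff(wt_ids, mut_ids)
  skipped_len <- sum(wt$exons$length[wt_ids %in% skipped])
  frameshift <- skipped_len %% 3 != 0
  twt <- translate_and_scan(wt)
  tmu <- translate_and_scan(mut)
  lcp <- 0L
  nmin <- min(twt$protein_length, tmu$protein_length)
  if (nmin > 0) {
    wch <- strsplit(twt$protein, "")[[1]]
    mch <- strsplit(tmu$protein, "")[[1]]
    neq <- which(wch[seq_len(nmin)] != mch[seq_len(nmin)])
    lcp <- if (length(neq)) neq[1] - 1L else nmin
  }
  ptc <- !tmu$nonstop && !is.na(tmu$stop_codon) &&
    tmu$protein_length < twt$protein_length
  structure(list(
    skipped_exons = skipped,
    frameshift = frameshift,
    aberrant_aa = tmu$protein_length - lcp,
    truncated_protein_length = tmu$protein_length,
    aa_lost = twt$protein_length - tmu$protein_length,
    ptc = ptc,
    ptc_transcript_pos = tmu$ptc_transcript_pos,
    nmd_candidate = if (!is.na(tmu$ptc_transcript_pos))
      nmd_flag(mut, tmu$ptc_transcript_pos, boundary_rule) else FALSE,
    nonstop = tmu$nonstop), class = "consequence_report")
}

#' @method print consequence_report
#' @export
print.consequence_report <- function(x, ...) {
  cat(sprintf("consequence_report: skip %s -> %s\n",
              paste(x$skipped_exons, collapse = ","),
              if (x$frameshift) "frameshift" else "in-frame"))
  cat(sprintf("  mutant protein %d aa (%d aberrant), %d aa lost; PTC: %s; NMD candidate: %s\n",
              x$truncated_protein_length, x$aberrant_aa, x$aa_lost, x$ptc,
              x$nmd_candidate))
  invisible(x)
}

#' Predict RT-PCR amplicon sizes across isoforms
#'
#' The amplicon length on an isoform is the inclusive distance between the
#' two primers' 5' ends on the spliced transcript (forward primer anchored
#' by exon and 1-based offset of its 5' end within the exon; reverse primer
#' likewise, its 5' end being the amplicon's last base). Isoforms lacking
#' either primer exon yield no amplicon.
#'
#' @param model a [transcript_model()] (one isoform).
#' @param fwd,rev lists `list(exon =, offset =)`.
#' @return amplicon length in bp, or NA when a primer exon is absent.
#' @export
insilico_rtpcr <- function(model, fwd, rev) {
  ids <- as.character(model$exons$id)
  if (!as.character(fwd$exon) %in% ids || !as.character(rev$exon) %in% ids)
    return(NA_integer_)
  starts <- exon_cumstart(model)
  p_f <- unname(starts[as.character(fwd$exon)]) + fwd$offset - 1L
  p_r <- unname(starts[as.character(rev$exon)]) + rev$offset - 1L
  if (p_r < p_f) return(NA_integer_)
  p_r - p_f + 1L
}

#' Nonsense-mediated decay candidacy
#'
#' A premature stop is an NMD candidate when it lies more than
#' `boundary_rule` nt upstream of the last exon-exon junction (the common
#' 50-nt rule); a stop in the final exon never is. Single-exon transcripts
#' are never candidates.
#'
#' @param model a [transcript_model()].
#' @param ptc_transcript_pos transcript position of the stop codon's first
#'   base.
#' @param boundary_rule distance threshold in nt (default 50).
#' @return logical.
#' @export
nmd_flag <- function(model, ptc_transcript_pos, boundary_rule = 50) {
  n_ex <- nrow(model$exons)
  if (n_ex < 2) return(FALSE)
  last_junction <- sum(model$exons$length[-n_ex])
  (last_junction - ptc_transcript_pos) > boundary_rule
}
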