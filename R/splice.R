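IUPAC_PY <- c("C", "T")
IUPAC_PU <- c("A", "G")

#' Score an intron 3' end against the acceptor consensus
#'
#' The splice-acceptor consensus is a pyrimidine hexamer, any base, then CAG
#' ending the intron (6Py-N-C-A-G). The terminal AG is invariant: without it
#' there is no match regardless of the mismatch budget. Non-pyrimidine bases
#' in the hexamer and a non-C at the consensus C position each consume one
#' mismatch.
#'
#' @param intron_3p at least the last 10 nt of the intron.
#' @param max_py_mismatch tolerated mismatches outside the AG (default 1).
#' @return list `match` (logical), `mismatches`, `ag_intact`.
#' @export
check_acceptor <- function(intron_3p, max_py_mismatch = 1) {
  s <- toupper(intron_3p)
  if (nchar(s) < 10) stopf("need >= 10 nt of intron 3' end")
  tail10 <- substr(s, nchar(s) - 9, nchar(s))
  b <- strsplit(tail10, "")[[1]]
  ag_intact <- b[9] == "A" && b[10] == "G"
  mism <- sum(!b[1:6] %in% IUPAC_PY) + as.integer(b[8] != "C")
  list(match = ag_intact && mism <= max_py_mismatch,
       mismatches = as.integer(mism), ag_intact = ag_intact)
}

bps_match_at <- function(b, a_pos) {
  ## branch A at position 6 of the 7-mer Py-N-Py-T-Pu-A-Py
  s <- a_pos - 5L
  if (s < 1 || a_pos + 1L > length(b)) return(FALSE)
  w <- b[s:(a_pos + 1L)]
  w[1] %in% IUPAC_PY && w[3] %in% IUPAC_PY && w[4] == "T" &&
    w[5] %in% IUPAC_PU && w[6] == "A" && w[7] %in% IUPAC_PY
}

#' Locate the branch-point sequence upstream of an acceptor
#'
#' Scans the intron upstream of the splice junction for the branch-point
#' consensus Py-N-Py-T-Pu-A-Py (branch A at position 6 of the 7-mer). The
#' offset convention is the distance from the branch A to the last intron
#' base, 1-based (branch A at the final intron base would be offset 1). The
#' canonical window (20-50 nt) is searched nearest-first; when it holds no
#' match the scan continues to `extended_limit` and any match found there is
#' flagged non-canonical.
#'
#' @param intron intron sequence (3' end at the junction).
#' @param window canonical offset window (default `c(20, 50)`).
#' @param extended_limit furthest offset searched (default 300).
#' @return list `offset` (NA when absent), `canonical`, `found`.
#' @export
find_bps <- function(intron, window = c(20, 50), extended_limit = 300) {
  b <- strsplit(toupper(intron), "")[[1]]
  n <- length(b)
  if (n < 7) stopf("intron too short for a branch-point scan")
  offsets <- seq(window[1], min(window[2], n))
  for (o in offsets) {
    if (bps_match_at(b, n - o + 1L))
      return(list(offset = o, canonical = TRUE, found = TRUE))
  }
  if (extended_limit > window[2]) {
    for (o in seq(window[2] + 1L, min(extended_limit, n))) {
      if (bps_match_at(b, n - o + 1L))
        return(list(offset = o, canonical = FALSE, found = TRUE))
    }
  }
  list(offset = NA_integer_, canonical = FALSE, found = FALSE)
}

#' Assess branch-point displacement by an intronic insertion
#'
#' An insertion landing between the branch point and the acceptor pushes the
#' branch point away from the junction by its full length; an insertion
#' upstream of the branch point leaves the offset unchanged. The site is
#' classified `disrupted` when the insertion displaces the branch point and
#' leaves it beyond the canonical maximum (pushed past its optimal
#' position), the mechanism by which a near-acceptor SINE insertion causes
#' exon skipping. A branch point that already sat outside the canonical
#' window in the wildtype (a functional non-canonical site) is not called
#' disrupted unless the insertion moved it.
#'
#' @param bps_offset_wt wildtype branch-A-to-junction offset (nt).
#' @param insertion_offset_upstream insertion site, nt upstream of the
#'   acceptor (e.g. 15 for an insertion between -15 and -16).
#' @param insertion_length inserted bases (bp).
#' @param canonical_max disruption threshold (default 50, the canonical
#'   window maximum).
#' @return list of class `splice_impact_report`: `bps_offset_wt`,
#'   `bps_offset_mut`, `displacement`, `disrupted`, `acceptor_ag_intact`.
#' @export
assess_insertion <- function(bps_offset_wt, insertion_offset_upstream,
                             insertion_length, canonical_max = 50) {
  stopifnot(bps_offset_wt > 0, insertion_offset_upstream > 0,
            insertion_length >= 0)
  between <- insertion_offset_upstream < bps_offset_wt
  mut <- if (between) bps_offset_wt + insertion_length else bps_offset_wt
  structure(list(
    bps_offset_wt = bps_offset_wt,
    bps_offset_mut = mut,
    displacement = mut - bps_offset_wt,
    disrupted = mut > bps_offset_wt && mut > canonical_max,
    ## an insertion >= 3 nt upstream of the junction leaves the terminal AG
    acceptor_ag_intact = insertion_offset_upstream >= 3),
    class = "splice_impact_report")
}

#' @method print splice_impact_report
#' @export
print.splice_impact_report <- function(x, ...) {
  cat(sprintf(paste0("splice_impact_report: branch point %d -> %d nt from ",
                     "the acceptor (displacement %d)\n"),
              x$bps_offset_wt, x$bps_offset_mut, x$displacement))
  cat(sprintf("  disrupted: %s; acceptor AG intact: %s\n", x$disrupted,
              x$acceptor_ag_intact))
  invisible(x)
}

#' JSON report for a splice-impact assessment
#' @param report a `splice_impact_report`.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
splice_report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
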