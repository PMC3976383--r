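## Per-marker shared allele: the allele homozygous in the plurality of cases,
## ties broken lexicographically; NA where no case is homozygous.
shared_alleles <- function(table, case_idx) {
  vapply(seq_len(ncol(table$a1)), function(j) {
    a1 <- table$a1[case_idx, j]; a2 <- table$a2[case_idx, j]
    hom <- !is.na(a1) & a1 == a2
    if (!any(hom)) return(NA_character_)
    tab <- table(a1[hom])
    names(tab)[order(-tab, names(tab))][1]
  }, character(1))
}

#' Scan for case-homozygous critical regions
#'
#' Finds maximal marker intervals in which a large fraction of cases is
#' homozygous for the per-marker shared allele (the allele homozygous in the
#' plurality of cases, lexicographic tie-break), no control is homozygous for
#' that shared haplotype across the interval, and no obligate carrier is
#' homozygous for it either. A case supports an interval when it has at most
#' `case_mismatch_tolerance` markers in the interval at which it is not
#' homozygous for the shared allele (missing calls count toward the
#' tolerance). Regions are ranked by bp span, longest first.
#'
#' @param table a [genotype_table()] with markers sorted by position within
#'   chromosome.
#' @param min_case_fraction minimum supporting-case fraction (default 0.65,
#'   the majority-of-cases regime).
#' @param case_mismatch_tolerance tolerated mismatching/missing markers per
#'   case (default 1).
#' @return data.frame of class `critical_regions`: `chrom`, `start_bp`,
#'   `end_bp` (positions of the flanking markers, 1-based inclusive),
#'   `length_bp` (= end - start), `n_markers`, `case_fraction`, `violations`
#'   (tolerated mismatches summed over supporting cases) and a list-column
#'   `supporting_cases`.
#' @export
scan_regions <- function(table, min_case_fraction = 0.65,
                         case_mismatch_tolerance = 1) {
  st <- table$samples$status
  case_idx <- which(st == "case")
  if (length(case_idx) == 0) stopf("scan_regions: no cases in cohort")
  ctrl_idx <- which(st == "control")
  carr_idx <- which(st == "obligate_carrier")
  out <- list()
  for (chr in unique(table$markers$chrom)) {
    j <- which(table$markers$chrom == chr)
    if (is.unsorted(table$markers$pos[j], strictly = FALSE))
      stopf("markers on chromosome %s are not position-sorted", chr)
    sub <- subset_markers(table, j)
    out[[chr]] <- scan_regions_chrom(sub, case_idx, ctrl_idx, carr_idx,
                                     min_case_fraction,
                                     case_mismatch_tolerance)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) {
    res <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), length_bp = integer(),
                      n_markers = integer(), case_fraction = numeric(),
                      violations = integer())
    res$supporting_cases <- list()
  } else {
    res <- res[order(-res$length_bp), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("critical_regions", "data.frame")
  res
}

scan_regions_chrom <- function(table, case_idx, ctrl_idx, carr_idx,
                               min_frac, tol) {
  m <- ncol(table$a1)
  n_cases <- length(case_idx)
  shared <- shared_alleles(table, case_idx)
  ## mismatch indicator per case x marker (missing or non-hom-shared)
  hom_sh <- function(idx) {
    sapply(seq_len(m), function(j) {
      if (is.na(shared[j])) return(rep(FALSE, length(idx)))
      !is.na(table$a1[idx, j]) & table$a1[idx, j] == shared[j] &
        table$a2[idx, j] == shared[j]
    })
  }
  mism <- !matrix(hom_sh(case_idx), nrow = n_cases)
  cs <- apply(mism, 1, cumsum)
  if (m == 1) cs <- matrix(cs, nrow = 1)
  cum <- cbind(0, t(cs))                       # n_cases x (m+1)
  s_need <- ceiling(min_frac * n_cases - 1e-9)
  ctrl_hom <- if (length(ctrl_idx)) matrix(hom_sh(ctrl_idx),
                                           nrow = length(ctrl_idx)) else NULL
  carr_hom <- if (length(carr_idx)) matrix(hom_sh(carr_idx),
                                           nrow = length(carr_idx)) else NULL
  ## longest all-hom run starting at i, per constrained sample
  run_end <- function(hom) {
    ## hom: n x m logical; returns n x m matrix E[s,i] = last j >= i-1 with
    ## hom at all of i..j (i-1 means not hom at i)
    n <- nrow(hom)
    E <- matrix(0L, n, m)
    for (s in seq_len(n)) {
      e <- integer(m)
      nxt <- m + 1L
      for (i in m:1) {
        if (!hom[s, i]) nxt <- i
        e[i] <- nxt - 1L
      }
      E[s, ] <- e
    }
    E
  }
  Ec <- if (!is.null(ctrl_hom)) run_end(ctrl_hom) else NULL
  Ek <- if (!is.null(carr_hom)) run_end(carr_hom) else NULL
  cand <- list()
  for (i in seq_len(m)) {
    ## per case: furthest j with <= tol mismatches in [i..j]
    lim <- tol + cum[, i]
    Jk <- vapply(seq_len(n_cases), function(k) {
      ## cum[k, j+1] <= lim[k]; cum row is nondecreasing
      findInterval(lim[k], cum[k, ]) - 1L
    }, numeric(1))
    if (s_need > 0) {
      jmax <- sort(Jk, decreasing = TRUE)[s_need]
    } else jmax <- m
    jmax <- min(jmax, m)
    if (jmax < i) next
    lo <- i
    if (!is.null(Ec)) lo <- max(lo, max(Ec[, i]) + 1L)
    if (!is.null(Ek)) lo <- max(lo, max(Ek[, i]) + 1L)
    if (jmax < lo) next
    cand[[length(cand) + 1]] <- c(i = i, j = as.integer(jmax))
  }
  if (length(cand) == 0) return(NULL)
  cm <- do.call(rbind, cand)
  keep <- rep(TRUE, nrow(cm))
  for (a in seq_len(nrow(cm))) {
    for (b in seq_len(nrow(cm))) {
      if (a != b && cm[b, "i"] <= cm[a, "i"] && cm[b, "j"] >= cm[a, "j"] &&
          !(cm[b, "i"] == cm[a, "i"] && cm[b, "j"] == cm[a, "j"])) {
        keep[a] <- FALSE; break
      }
    }
  }
  cm <- cm[keep, , drop = FALSE]
  cm <- cm[!duplicated(cm), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cm)), function(r) {
    i <- cm[r, "i"]; j <- cm[r, "j"]
    mm <- cum[, j + 1] - cum[, i]
    supp <- which(mm <= tol)
    df <- data.frame(chrom = table$markers$chrom[1],
                     start_bp = table$markers$pos[i],
                     end_bp = table$markers$pos[j],
                     length_bp = table$markers$pos[j] - table$markers$pos[i],
                     n_markers = j - i + 1L,
                     case_fraction = length(supp) / n_cases,
                     violations = as.integer(sum(mm[supp])),
                     stringsAsFactors = FALSE)
    df$supporting_cases <- list(table$samples$id[case_idx][supp])
    df
  })
  do.call(rbind, rows)
}

#' Region span in megabases
#'
#' `(end_bp - start_bp) / 1e6`, rounded to 3 decimals — the marker-bounded
#' span convention (63.935 to 67.729 Mb spans 3.794 Mb).
#'
#' @param region one row of a `critical_regions` data.frame (or any object
#'   with `start_bp` and `end_bp`).
#' @return span in Mb.
#' @export
region_length <- function(region) {
  round((region$end_bp - region$start_bp) / 1e6, 3)
}

#' Classify samples over a marker interval
#'
#' For the shared-case haplotype of a marker interval, classifies every
#' sample as `hom_shared` (homozygous for the shared allele at every
#' genotyped interval marker), `het` (heterozygous at >= 1 marker),
#' `hom_other` (homozygous non-shared somewhere, never heterozygous) or
#' `missing` (no genotyped interval marker).
#'
#' @param table a [genotype_table()].
#' @param chrom chromosome of the interval.
#' @param start_bp,end_bp interval bounds (1-based inclusive).
#' @return named character vector, one classification per sample.
#' @export
genotype_at_interval <- function(table, chrom, start_bp, end_bp) {
  j <- which(table$markers$chrom == chrom & table$markers$pos >= start_bp &
               table$markers$pos <= end_bp)
  if (length(j) == 0) stopf("interval contains no markers")
  sub <- subset_markers(table, j)
  shared <- shared_alleles(sub, which(sub$samples$status == "case"))
  out <- vapply(seq_len(nrow(sub$samples)), function(i) {
    a1 <- sub$a1[i, ]; a2 <- sub$a2[i, ]
    ok <- !is.na(a1)
    if (!any(ok)) return("missing")
    if (any(a1[ok] != a2[ok])) return("het")
    hom_sh <- ok & !is.na(shared) & a1 == shared & a2 == shared
    if (all(hom_sh[ok])) "hom_shared" else "hom_other"
  }, character(1))
  stats::setNames(out, sub$samples$id)
}

#' Write critical regions as BED
#'
#' Converts the internal 1-based inclusive marker-bounded coordinates to
#' BED's 0-based half-open convention (`start - 1`, `end`).
#'
#' @param regions a `critical_regions` data.frame.
#' @param path output BED path.
#' @return invisibly, the path.
#' @export
regions_to_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start_bp - 1L,
                    end = regions$end_bp,
                    name = sprintf("region_%d", seq_len(nrow(regions))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
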