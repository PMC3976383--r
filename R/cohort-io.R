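#' Construct a genotype table
#'
#' The central container of the mapping stages: an ordered sample sheet, an
#' ordered marker map and two allele matrices holding the unordered diploid
#' call per (sample, marker). Genotypes are unphased; the two allele matrices
#' are stored sorted (`a1 <= a2` stringwise) so that unordered-pair equality
#' is plain elementwise comparison. Missing calls are `NA` in both matrices.
#'
#' @param samples data.frame with columns `id`, `status` (one of `case`,
#'   `control`, `obligate_carrier`, `unknown`) and optionally `breed`,
#'   `age_at_exam`.
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based bp)
#'   and optionally `kind` (`SNP` or `microsatellite`; default `SNP`).
#' @param a1,a2 character matrices, samples x markers.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(samples, markers, a1, a2) {
  stopifnot(is.data.frame(samples), is.data.frame(markers))
  if (!all(samples$status %in% STATUS_LEVELS))
    stopf("sample status must be one of: %s", paste(STATUS_LEVELS, collapse = ", "))
  if (is.null(markers$kind)) markers$kind <- "SNP"
  if (any(markers$pos < 1)) stopf("marker positions must be >= 1")
  if (anyDuplicated(samples$id)) stopf("duplicate sample ids")
  if (anyDuplicated(markers$id)) stopf("duplicate marker ids")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!all(dim(a1) == c(nrow(samples), nrow(markers))) ||
      !all(dim(a2) == dim(a1)))
    stopf("allele matrices must be %d samples x %d markers",
          nrow(samples), nrow(markers))
  if (!identical(unname(is.na(a1)), unname(is.na(a2))))
    stopf("half-missing calls are not allowed")
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(samples$id, markers$id)
  structure(list(samples = samples, markers = markers, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @method print genotype_table
#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d markers (call rate %.4f)\n",
              nrow(x$samples), nrow(x$markers), call_rate(x)))
  cat("  status:", paste(sprintf("%s=%d", names(table(x$samples$status)),
                                 table(x$samples$status)), collapse = " "), "\n")
  invisible(x)
}

#' @method dim genotype_table
#' @export
dim.genotype_table <- function(x) c(nrow(x$samples), nrow(x$markers))

#' Fraction of non-missing calls
#' @param table a `genotype_table`.
#' @return fraction in \[0, 1\].
#' @export
call_rate <- function(table) {
  mean(!is.na(table$a1))
}

#' Read a PED/MAP genotype table
#'
#' Text dialect: the PED file has one row per sample — sample id, status code
#' (1 = control, 2 = case, 3 = obligate carrier, 0 = unknown), then two
#' whitespace-separated allele columns per marker, with "0 0" for a missing
#' call. The MAP file has one row per marker: marker id, chromosome, bp
#' position and an optional 4th column `kind` (`SNP`/`microsatellite`,
#' default `SNP`). Positions are 1-based.
#'
#' @param ped_path,map_path file paths.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stopf("PED file not found: %s", ped_path)
  if (!file.exists(map_path)) stopf("MAP file not found: %s", map_path)
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (!ncol(map) %in% c(3L, 4L)) stopf("MAP must have 3 or 4 columns")
  markers <- data.frame(id = map[[1]], chrom = map[[2]],
                        pos = as.integer(map[[3]]),
                        kind = if (ncol(map) == 4) map[[4]] else "SNP",
                        stringsAsFactors = FALSE)
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  m <- nrow(markers)
  if (ncol(ped) != 2 + 2 * m)
    stopf("PED has %d columns; expected %d for %d markers",
          ncol(ped), 2 + 2 * m, m)
  samples <- data.frame(id = ped[[1]],
                        status = status_from_code(as.integer(ped[[2]])),
                        stringsAsFactors = FALSE)
  al <- as.matrix(ped[, -(1:2), drop = FALSE])
  a1 <- al[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, by = 2), drop = FALSE]
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  if (!identical(unname(is.na(a1)), unname(is.na(a2))))
    stopf("half-missing call in PED (one allele '0')")
  genotype_table(samples, markers, a1, a2)
}

#' Write a genotype table as PED/MAP text
#' @param table a `genotype_table`.
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genotypes <- function(table, ped_path, map_path) {
  mk <- table$markers
  utils::write.table(mk[, c("id", "chrom", "pos", "kind")], map_path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  a1 <- table$a1; a2 <- table$a2
  a1[is.na(a1)] <- "0"; a2[is.na(a2)] <- "0"
  m <- ncol(a1)
  inter <- matrix("", nrow(a1), 2 * m)
  inter[, seq(1, 2 * m, by = 2)] <- a1
  inter[, seq(2, 2 * m, by = 2)] <- a2
  out <- cbind(table$samples$id, status_to_code(table$samples$status), inter)
  utils::write.table(out, ped_path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Per-marker minor allele frequency
#'
#' Missing calls are excluded from numerator and denominator. Multiallelic
#' markers report the frequency of their rarest observed allele; markers with
#' no observed calls report `NA`.
#'
#' @param table a `genotype_table`.
#' @return numeric vector, one MAF per marker.
#' @export
marker_maf <- function(table) {
  vapply(seq_len(ncol(table$a1)), function(j) {
    al <- c(table$a1[, j], table$a2[, j])
    al <- al[!is.na(al)]
    if (length(al) == 0) return(NA_real_)
    tab <- table(al)
    if (length(tab) < 2) return(0)
    min(tab) / length(al)
  }, numeric(1))
}

#' Per-marker missingness
#' @param table a `genotype_table`.
#' @return fraction of samples with a missing call, per marker.
#' @export
marker_missingness <- function(table) {
  colMeans(is.na(table$a1))
}

#' Filter markers on MAF and missingness
#'
#' Retains markers with minor allele frequency `>= maf_min` and missingness
#' `<= miss_max`. The MAF condition applies to SNPs only: microsatellites
#' were added for information content and pass through regardless of allele
#' frequencies (they are still subject to the missingness cap). Sample order
#' is unchanged; the operation is idempotent.
#'
#' @param table a `genotype_table`.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param miss_max maximum missingness fraction (default 0.10).
#' @return the filtered `genotype_table`.
#' @export
filter_markers <- function(table, maf_min = 0.05, miss_max = 0.10) {
  stopifnot(maf_min >= 0, maf_min <= 1, miss_max >= 0, miss_max <= 1)
  if (ncol(table$a1) == 0) return(table)
  maf <- marker_maf(table)
  miss <- marker_missingness(table)
  is_snp <- table$markers$kind == "SNP"
  keep <- (!is_snp | (!is.na(maf) & maf >= maf_min)) & miss <= miss_max
  subset_markers(table, which(keep))
}

subset_markers <- function(table, j) {
  genotype_table(table$samples, table$markers[j, , drop = FALSE],
                 table$a1[, j, drop = FALSE], table$a2[, j, drop = FALSE])
}

subset_samples <- function(table, i) {
  genotype_table(table$samples[i, , drop = FALSE], table$markers,
                 table$a1[i, , drop = FALSE], table$a2[i, , drop = FALSE])
}

#' Load a screening-panel count table
#'
#' TSV with a `status` column and one column per genotype class (`hom_ins`,
#' `het`, `hom_wt`); one row per clinical status. Counts must be
#' non-negative integers.
#'
#' @param tsv_path path to the TSV.
#' @return a `screening_panel`: list with `counts` (matrix status x class),
#'   `breed` and `total`.
#' @export
load_screening_panel <- function(tsv_path) {
  if (!file.exists(tsv_path)) stopf("panel file not found: %s", tsv_path)
  df <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  screening_panel(df, breed = attr(df, "breed") %||% NA_character_)
}

#' Construct a screening panel from a count data.frame
#' @param df data.frame with column `status` and genotype-class count columns.
#' @param breed optional breed label.
#' @return a `screening_panel`.
#' @export
screening_panel <- function(df, breed = NA_character_) {
  classes <- c("hom_ins", "het", "hom_wt")
  if (!"status" %in% names(df)) stopf("panel needs a 'status' column")
  missing_cls <- setdiff(classes, names(df))
  for (cl in missing_cls) df[[cl]] <- 0L
  counts <- as.matrix(df[, classes, drop = FALSE])
  if (any(counts < 0)) stopf("negative count in screening panel")
  if (any(counts != round(counts))) stopf("non-integer count in screening panel")
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$status
  structure(list(counts = counts, breed = breed, total = sum(counts)),
            class = "screening_panel")
}

#' @method print screening_panel
#' @export
print.screening_panel <- function(x, ...) {
  cat(sprintf("screening_panel (%s): %d dogs\n",
              ifelse(is.na(x$breed), "breed unknown", x$breed), x$total))
  print(x$counts)
  invisible(x)
}

#' Read a pedigree file
#'
#' 4-column TSV (`id`, `sire`, `dam`, `status`) with an optional 5th
#' `genotype` column (`hom_ins`, `het`, `hom_wt`); `0` or empty marks a
#' missing parent, status or genotype. The parent graph must be acyclic.
#'
#' @param path pedigree TSV path.
#' @return a data.frame of class `pedigree`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_pedigree(df)
}

#' Validate and class a pedigree data.frame
#' @param df data.frame with columns `id`, `sire`, `dam`, `status` and
#'   optionally `genotype`.
#' @return the validated data.frame with class `pedigree`.
#' @export
as_pedigree <- function(df) {
  need <- c("id", "sire", "dam", "status")
  if (!all(need %in% names(df))) stopf("pedigree needs columns %s",
                                       paste(need, collapse = ", "))
  for (col in c("sire", "dam", "status"))
    df[[col]][df[[col]] %in% c("0", "", NA)] <- NA
  if (is.null(df$genotype)) df$genotype <- NA_character_
  df$genotype[df$genotype %in% c("0", "")] <- NA
  ## cycle check: repeatedly strip members whose parents are all resolved
  resolved <- character(0)
  remaining <- df$id
  repeat {
    ok <- remaining[vapply(remaining, function(i) {
      r <- df[df$id == i, ]
      all(is.na(c(r$sire, r$dam)) | c(r$sire, r$dam) %in% resolved |
            !c(r$sire, r$dam) %in% df$id)
    }, logical(1))]
    if (length(ok) == 0) break
    resolved <- c(resolved, ok)
    remaining <- setdiff(remaining, ok)
  }
  if (length(remaining) > 0)
    stopf("pedigree contains a cycle involving: %s",
          paste(remaining, collapse = ", "))
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Write a pedigree TSV
#' @param ped a `pedigree`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  for (col in c("sire", "dam", "status", "genotype"))
    out[[col]][is.na(out[[col]])] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
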