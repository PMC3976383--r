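#' Construct a variant call set
#'
#' @param info data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; a `class` column (`SNP`, `indel`, `insertion`) is derived from
#'   ref/alt when absent.
#' @param gt character matrix (variants x samples) of genotype states
#'   `hom_ref`, `het`, `hom_alt` or `missing`.
#' @return object of class `variant_calls`.
#' @export
variant_calls <- function(info, gt) {
  stopifnot(is.data.frame(info), nrow(info) == nrow(gt))
  if (any(info$pos < 1)) stopf("variant positions must be >= 1")
  gt <- as.matrix(gt)
  bad <- !gt %in% c("hom_ref", "het", "hom_alt", "missing")
  if (any(bad)) stopf("invalid genotype state(s): %s",
                      paste(unique(gt[bad]), collapse = ", "))
  if (is.null(info$class)) {
    info$class <- ifelse(grepl("^<", info$alt) |
                           nchar(info$alt) > nchar(info$ref), "insertion",
                         ifelse(nchar(info$ref) == 1 & nchar(info$alt) == 1,
                                "SNP", "indel"))
  }
  structure(list(info = info, gt = gt), class = "variant_calls")
}

gt_code_to_state <- function(gt) {
  gt <- sub(":.*", "", gt)
  gt <- gsub("\\|", "/", gt)
  out <- rep("missing", length(gt))
  out[gt %in% "0/0"] <- "hom_ref"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt %in% "1/1"] <- "hom_alt"
  out
}

#' Read variant calls from a VCF
#'
#' Parses a VCF (plain or bgzipped) via `vcfR` and reduces each sample's GT
#' field to `hom_ref` / `het` / `hom_alt` / `missing`. Sample clinical status
#' is never taken from the VCF; pair the result with a cohort sample sheet.
#'
#' @param vcf_path path to a VCF file.
#' @return a [variant_calls()] object.
#' @export
read_variant_calls <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  info <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(gt_code_to_state(gt_raw), nrow = nrow(info),
               dimnames = dimnames(gt_raw))
  gt[is.na(gt_raw)] <- "missing"
  variant_calls(info, gt)
}

#' Write variant calls as VCF text
#' @param calls a [variant_calls()] object.
#' @param path output path (uncompressed VCF).
#' @return invisibly, the path.
#' @export
write_variant_calls <- function(calls, path) {
  gt_out <- matrix(c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                     missing = "./.")[calls$gt], nrow = nrow(calls$info))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(calls$gt)), collapse = "\t"))
  body <- vapply(seq_len(nrow(calls$info)), function(i) {
    paste(c(calls$info$chrom[i], calls$info$pos[i], ".", calls$info$ref[i],
            calls$info$alt[i], ".", "PASS", ".", "GT", gt_out[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter variants on the recessive segregation pattern
#'
#' Retains exactly the calls that are homozygous for the alternate allele in
#' every case, heterozygous in every obligate carrier and homozygous
#' reference in every control. By default a missing genotype in any such
#' pivotal sample excludes the variant; with `permissive = TRUE` missing is
#' treated as compatible. Unknown-status samples are ignored.
#'
#' @param calls a [variant_calls()] object.
#' @param samples data.frame with `id` and `status` covering the genotyped
#'   samples.
#' @param permissive treat missing genotypes as compatible (default FALSE).
#' @return the retained `variant_calls`.
#' @export
segregation_filter <- function(calls, samples, permissive = FALSE) {
  ids <- colnames(calls$gt)
  st <- samples$status[match(ids, samples$id)]
  if (anyNA(st)) stopf("samples missing from cohort sheet: %s",
                       paste(ids[is.na(st)], collapse = ", "))
  if (!any(st == "case")) stopf("segregation_filter: no cases in cohort")
  want <- c(case = "hom_alt", obligate_carrier = "het", control = "hom_ref")
  keep <- rep(TRUE, nrow(calls$info))
  for (role in names(want)) {
    cols <- which(st == role)
    if (length(cols) == 0) next
    g <- calls$gt[, cols, drop = FALSE]
    ok <- g == want[[role]]
    if (permissive) ok <- ok | g == "missing"
    keep <- keep & rowSums(!ok) == 0
  }
  variant_calls(calls$info[keep, , drop = FALSE],
                calls$gt[keep, , drop = FALSE])
}

#' Filter variants on exon proximity
#'
#' Retains calls located inside an exon of the gene model or within
#' `window_bp` of an exon boundary. The model must carry genomic exon
#' coordinates (`gstart`/`gend` columns, 1-based inclusive, same coordinate
#' system as the calls).
#'
#' @param calls a [variant_calls()] object.
#' @param gene_model a [transcript_model()] with genomic exon coordinates.
#' @param window_bp distance cutoff in bp (default 50, covering canonical
#'   splice motifs and near-acceptor insertions).
#' @return the retained `variant_calls`.
#' @export
proximity_filter <- function(calls, gene_model, window_bp = 50) {
  ex <- gene_model$exons
  if (is.null(ex$gstart) || is.null(ex$gend))
    stopf("gene model lacks genomic exon coordinates")
  dmin <- vapply(calls$info$pos, function(p) {
    d <- ifelse(p >= ex$gstart & p <= ex$gend, 0,
                pmin(abs(p - ex$gstart), abs(p - ex$gend)))
    min(d)
  }, numeric(1))
  keep <- dmin <= window_bp
  variant_calls(calls$info[keep, , drop = FALSE],
                calls$gt[keep, , drop = FALSE])
}
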