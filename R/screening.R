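#' Genotype-phenotype concordance under a recessive model
#'
#' Under the recessive model a case is concordant when homozygous for the
#' insertion, an obligate carrier when heterozygous, and a clinically clear
#' dog when heterozygous or homozygous wildtype. Dogs of unknown clinical
#' status get no concordance row. Percentages are rounded to one decimal,
#' half up. The "clinically free" group (clear dogs plus obligate carriers)
#' is summarized by its het and hom-wildtype percentages.
#'
#' @param panel a [screening_panel()].
#' @param model inheritance model; only `"recessive"` is implemented.
#' @return list of class `concordance_table`: `by_status` (data.frame:
#'   status, n, concordant, pct), `clinically_free` (n, het_pct,
#'   hom_wt_pct), `allele_frequency`, `counts`.
#' @export
concordance <- function(panel, model = "recessive") {
  model <- match.arg(model, "recessive")
  ct <- panel$counts
  concordant_of <- function(status, row) {
    switch(status,
           case = row["hom_ins"],
           obligate_carrier = row["het"],
           control = row["het"] + row["hom_wt"],
           NA_integer_)
  }
  rows <- lapply(rownames(ct), function(st) {
    n <- sum(ct[st, ])
    conc <- concordant_of(st, ct[st, ])
    if (is.na(conc) || n == 0) return(NULL)
    data.frame(status = st, n = n, concordant = unname(conc),
               pct = round_half_up(100 * conc / n, 1),
               stringsAsFactors = FALSE)
  })
  by_status <- do.call(rbind, rows)
  free_rows <- intersect(c("control", "obligate_carrier"), rownames(ct))
  free <- colSums(ct[free_rows, , drop = FALSE])
  n_free <- sum(free)
  clinically_free <- list(
    n = as.integer(n_free),
    het_pct = if (n_free > 0) round_half_up(100 * free[["het"]] / n_free, 1)
    else NA_real_,
    hom_wt_pct = if (n_free > 0)
      round_half_up(100 * free[["hom_wt"]] / n_free, 1) else NA_real_)
  structure(list(by_status = by_status, clinically_free = clinically_free,
                 allele_frequency = allele_frequency(panel), counts = ct),
            class = "concordance_table")
}

#' @method print concordance_table
#' @export
print.concordance_table <- function(x, ...) {
  cat("concordance_table (recessive model)\n")
  if (!is.null(x$by_status)) print(x$by_status, row.names = FALSE)
  cat(sprintf("  clinically free (n=%d): het %.1f%%, hom_wt %.1f%%\n",
              x$clinically_free$n, x$clinically_free$het_pct,
              x$clinically_free$hom_wt_pct))
  cat(sprintf("  insertion allele frequency: %.4f\n", x$allele_frequency))
  invisible(x)
}

#' Penetrance proxy: cases among insertion homozygotes
#'
#' The fraction of all insertion-homozygous dogs that have been diagnosed
#' affected, with dogs of unknown clinical status kept in the denominator.
#' Reported as a half-up one-decimal percentage.
#'
#' @param panel a [screening_panel()].
#' @return list `pct`, `cases`, `hom_ins_total`.
#' @export
penetrance_proxy <- function(panel) {
  ct <- panel$counts
  total <- sum(ct[, "hom_ins"])
  if (total == 0) stopf("no insertion homozygotes in panel")
  cases <- if ("case" %in% rownames(ct)) ct["case", "hom_ins"] else 0L
  list(pct = round_half_up(100 * cases / total, 1),
       cases = unname(cases), hom_ins_total = unname(total))
}

#' Insertion allele frequency in a panel
#'
#' `(2 * hom_ins + het) / (2 * N)` over all genotyped dogs.
#'
#' @param panel a [screening_panel()].
#' @return frequency in \[0, 1\].
#' @export
allele_frequency <- function(panel) {
  ct <- panel$counts
  n <- sum(ct)
  if (n == 0) stopf("empty panel")
  (2 * sum(ct[, "hom_ins"]) + sum(ct[, "het"])) / (2 * n)
}

#' Check a genotyped pedigree against recessive inheritance
#'
#' Reports violations of the autosomal-recessive, fully-penetrant model:
#' (i) an affected dog not homozygous for the insertion; (ii) an offspring
#' carrying insertion allele(s) its genotyped parents cannot have supplied
#' (het with both parents genotyped hom_wt, or hom_ins with any genotyped
#' parent hom_wt); (iii) a non-hom_ins offspring of two hom_ins parents;
#' (iv) a hom_ins dog of known clinical status that is unaffected.
#' Ungenotyped members are skipped.
#'
#' @param ped a [as_pedigree()] data.frame with a `genotype` column.
#' @return data.frame `member`, `rule`, `detail` (zero rows when consistent).
#' @export
pedigree_recessive_check <- function(ped) {
  v <- list()
  add <- function(member, rule, detail)
    v[[length(v) + 1]] <<- data.frame(member = member, rule = rule,
                                      detail = detail,
                                      stringsAsFactors = FALSE)
  gt <- stats::setNames(ped$genotype, ped$id)
  st <- stats::setNames(ped$status, ped$id)
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]; g <- gt[[id]]
    if (is.na(g)) next
    if (!is.na(st[[id]]) && st[[id]] == "case" && g != "hom_ins")
      add(id, "i", sprintf("affected but %s", g))
    if (!is.na(st[[id]]) && st[[id]] != "case" && st[[id]] != "unknown" &&
        g == "hom_ins")
      add(id, "iv", "hom_ins but not affected")
    parents <- c(ped$sire[i], ped$dam[i])
    pg <- gt[parents[!is.na(parents) & parents %in% ped$id]]
    pg <- pg[!is.na(pg)]
    if (length(pg)) {
      if (g == "het" && length(pg) == 2 && all(pg == "hom_wt"))
        add(id, "ii", "het offspring of two hom_wt parents")
      if (g == "hom_ins" && any(pg == "hom_wt"))
        add(id, "ii", "hom_ins offspring of a hom_wt parent")
      if (g != "hom_ins" && length(pg) == 2 && all(pg == "hom_ins"))
        add(id, "iii", "non-hom_ins offspring of two hom_ins parents")
    }
  }
  if (length(v) == 0)
    return(data.frame(member = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Write a concordance report
#' @param tab a `concordance_table`.
#' @param json_path,tsv_path output paths.
#' @return invisibly, the paths.
#' @export
write_concordance <- function(tab, json_path, tsv_path) {
  jsonlite::write_json(list(by_status = tab$by_status,
                            clinically_free = tab$clinically_free,
                            allele_frequency = tab$allele_frequency),
                       json_path, auto_unbox = TRUE, digits = NA)
  utils::write.table(tab$by_status, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}
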