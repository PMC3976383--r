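#' Pairwise identity-by-state distance
#'
#' For each sample pair, 1 minus the shared-allele fraction over markers where
#' both samples are genotyped (per marker IBS is 0, 1 or 2 shared alleles out
#' of 2; genotypes are unordered pairs). A pair with no co-genotyped marker is
#' a validation error.
#'
#' @param table a [genotype_table()].
#' @return symmetric numeric matrix of distances in \[0, 1\].
#' @export
ibs_distance <- function(table) {
  n <- nrow(table$samples)
  if (n < 2) stopf("need >= 2 samples for IBS distances")
  a1 <- table$a1; a2 <- table$a2
  d <- matrix(0, n, n, dimnames = list(table$samples$id, table$samples$id))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ok <- !is.na(a1[i, ]) & !is.na(a1[j, ])
      if (!any(ok)) stopf("samples %s and %s share no genotyped marker",
                          table$samples$id[i], table$samples$id[j])
      full <- a1[i, ok] == a1[j, ok] & a2[i, ok] == a2[j, ok]
      part <- a1[i, ok] == a1[j, ok] | a1[i, ok] == a2[j, ok] |
        a2[i, ok] == a1[j, ok] | a2[i, ok] == a2[j, ok]
      ibs <- ifelse(full, 2, ifelse(part, 1, 0))
      d[i, j] <- d[j, i] <- 1 - mean(ibs) / 2
    }
  }
  d
}

#' Cluster samples on IBS distance
#'
#' Complete-linkage agglomerative clustering on the IBS distance matrix, cut
#' at a fixed number of clusters. Deterministic given the input order
#' (`stats::hclust` ties are broken by merge order).
#'
#' @param table a [genotype_table()].
#' @param max_clusters number of clusters K (>= 1).
#' @return named integer vector: sample id -> cluster index in 1..K.
#' @export
ibs_cluster <- function(table, max_clusters = 2) {
  stopifnot(max_clusters >= 1)
  ids <- table$samples$id
  if (max_clusters == 1)
    return(stats::setNames(rep(1L, length(ids)), ids))
  d <- ibs_distance(table)
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  stats::cutree(hc, k = max_clusters)[ids]
}

#' Allelic case-control chi-square test
#'
#' Pearson 1-df chi-square on a 2x2 allele-count table (rows case/control,
#' columns counted allele / other alleles), without continuity correction.
#' Degenerate tables (a zero margin) return statistic 0, p 1.
#'
#' @param counts 2x2 numeric matrix of allele counts.
#' @return list with `chi_square` and `p_raw`.
#' @export
allelic_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stopf("allelic_test: zero total count")
  r <- rowSums(counts); cc <- colSums(counts)
  denom <- prod(r) * prod(cc)
  chi <- if (denom == 0) 0 else
    n * (counts[1, 1] * counts[2, 2] - counts[1, 2] * counts[2, 1])^2 / denom
  list(chi_square = chi, p_raw = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Stratified Cochran-Mantel-Haenszel allelic test
#'
#' 1-df CMH statistic over K 2x2 allele-count strata, without continuity
#' correction. The per-stratum variance uses an n^3 denominator so that with
#' a single stratum the statistic equals the Pearson allelic chi-square
#' exactly (see the methods vignette); it agrees with the classical
#' hypergeometric form up to a factor (n-1)/n per stratum. Strata with zero
#' total are skipped with a warning.
#'
#' @param tables 2x2xK array (or a single 2x2 matrix).
#' @return list with `chi_square` and `p_raw`.
#' @export
cmh_test <- function(tables) {
  if (is.matrix(tables)) tables <- array(tables, c(2, 2, 1))
  stopifnot(length(dim(tables)) == 3, all(dim(tables)[1:2] == 2))
  num <- 0; den <- 0
  for (k in seq_len(dim(tables)[3])) {
    t2 <- tables[, , k]
    n <- sum(t2)
    if (n == 0) {
      warning(sprintf("cmh_test: stratum %d has zero total; skipped", k))
      next
    }
    r <- rowSums(t2); cc <- colSums(t2)
    num <- num + t2[1, 1] - r[1] * cc[1] / n
    den <- den + r[1] * r[2] * cc[1] * cc[2] / n^3
  }
  chi <- if (den == 0) 0 else unname(num^2 / den)
  list(chi_square = chi, p_raw = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Genomic inflation factor
#'
#' Lambda is the median observed 1-df chi-square statistic divided by the
#' null median `qchisq(0.5, 1)` (about 0.4549). Lambda well above 1 indicates
#' population stratification.
#'
#' @param chi_squares numeric vector of 1-df chi-square statistics.
#' @return lambda (positive scalar).
#' @export
inflation_factor <- function(chi_squares) {
  if (length(chi_squares) == 0) stopf("inflation_factor: no statistics")
  stats::median(chi_squares) / stats::qchisq(0.5, df = 1)
}

## Dosage of the counted (lexicographically first observed) allele, per
## sample x marker; NA where the call is missing. The allelic chi-square is
## invariant to which allele is counted (column swap of the 2x2).
dosage_matrix <- function(table) {
  a1 <- table$a1; a2 <- table$a2
  m <- ncol(a1)
  D <- matrix(NA_real_, nrow(a1), m, dimnames = dimnames(a1))
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    al <- al[!is.na(al)]
    if (length(al) == 0) next
    counted <- min(al)
    D[, j] <- (a1[, j] == counted) + (a2[, j] == counted)
  }
  D
}

## Per-marker CMH statistics for one or many case/control label assignments.
## Y: n_perm x n 0/1 case-indicator matrix over the case/control samples;
## D: n x m dosage matrix (NA = missing). Returns n_perm x m chi-squares.
cmh_stat_matrix <- function(Y, D, strata) {
  n_perm <- nrow(Y); m <- ncol(D)
  NM <- (!is.na(D)) * 1
  D0 <- D; D0[is.na(D0)] <- 0
  num <- matrix(0, n_perm, m)
  den <- matrix(0, n_perm, m)
  for (k in unique(strata)) {
    idx <- which(strata == k)
    Dk <- D0[idx, , drop = FALSE]
    NMk <- NM[idx, , drop = FALSE]
    C1 <- colSums(Dk)                  # counted-allele total, fixed
    N  <- 2 * colSums(NMk)             # chromosomes genotyped, fixed
    Yk <- Y[, idx, drop = FALSE]
    A  <- Yk %*% Dk                    # counted alleles in cases
    R1 <- 2 * (Yk %*% NMk)             # case chromosomes genotyped
    Np <- matrix(N, n_perm, m, byrow = TRUE)
    C1p <- matrix(C1, n_perm, m, byrow = TRUE)
    ok <- Np > 0
    E <- matrix(0, n_perm, m); V <- matrix(0, n_perm, m)
    E[ok] <- (R1 * C1p / Np)[ok]
    V[ok] <- (R1 * (Np - R1) * C1p * (Np - C1p) / Np^3)[ok]
    num <- num + (A - E)
    den <- den + V
  }
  stat <- matrix(0, n_perm, m)
  pos <- den > 0
  stat[pos] <- num[pos]^2 / den[pos]
  stat
}

#' Genome-wide max(T) permutation p-values
#'
#' Permutes case/control labels within clusters and compares each marker's
#' observed CMH statistic with the permutation distribution of the
#' genome-wide maximum statistic:
#' `p_genome(m) = (1 + #{perm max >= observed_m}) / (1 + n_perm)`.
#' Ties count as exceedances (conservative); the +1 smoothing keeps p > 0.
#' Obligate carriers and unknown-status samples are excluded. Clusters whose
#' samples all share one status permute as no-ops (noted via message).
#'
#' @param table a [genotype_table()].
#' @param clusters named cluster assignment from [ibs_cluster()] (default:
#'   one cluster).
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed (required; permutations are seeded and reproducible).
#' @return list with per-marker `chi_square`, `p_raw`, `p_genome`, plus
#'   `n_perm` and `seed`.
#' @export
maxt_permutation <- function(table, clusters = NULL, n_perm, seed) {
  stopifnot(n_perm >= 1)
  ids <- table$samples$id
  if (is.null(clusters)) clusters <- stats::setNames(rep(1L, length(ids)), ids)
  cc <- table$samples$status %in% c("case", "control")
  if (!any(table$samples$status == "case")) stopf("no cases in cohort")
  tab_cc <- subset_samples(table, which(cc))
  strata <- unname(clusters[tab_cc$samples$id])
  y_obs <- as.numeric(tab_cc$samples$status == "case")
  for (k in unique(strata)) {
    if (length(unique(y_obs[strata == k])) == 1)
      message(sprintf("cluster %s is single-status; permutations within it are no-ops", k))
  }
  D <- dosage_matrix(tab_cc)
  obs <- drop(cmh_stat_matrix(matrix(y_obs, nrow = 1), D, strata))
  set.seed(seed)
  Y <- matrix(0, n_perm, length(y_obs))
  for (p in seq_len(n_perm)) {
    yp <- y_obs
    for (k in unique(strata)) {
      idx <- which(strata == k)
      yp[idx] <- sample(yp[idx])
    }
    Y[p, ] <- yp
  }
  perm_stats <- cmh_stat_matrix(Y, D, strata)
  maxes <- apply(perm_stats, 1, max)
  p_genome <- vapply(obs, function(o) (1 + sum(maxes >= o)) / (1 + n_perm),
                     numeric(1))
  list(chi_square = obs,
       p_raw = stats::pchisq(obs, df = 1, lower.tail = FALSE),
       p_genome = p_genome, n_perm = n_perm, seed = seed)
}

#' Run a full association scan
#'
#' IBS clustering (K clusters), per-marker CMH allelic association across
#' clusters, max(T) permutation correction and the genomic inflation factor.
#' With `k_clusters = 1` the scan reduces to the unstratified allelic test.
#'
#' @param table a [genotype_table()].
#' @param k_clusters number of IBS clusters (default 2).
#' @param n_perm permutations for max(T) (default 1000).
#' @param seed RNG seed.
#' @return list of class `assoc_scan`: `result` (data.frame: id, chrom, pos,
#'   chi_square, p_raw, p_genome), `lambda`, `clusters`, `k`, `n_perm`,
#'   `seed`, and `bonferroni` (0.05 / n markers, reported for plotting
#'   parity, not used for inference).
#' @export
assoc_scan <- function(table, k_clusters = 2, n_perm = 1000, seed) {
  clusters <- ibs_cluster(table, max_clusters = k_clusters)
  mt <- maxt_permutation(table, clusters, n_perm = n_perm, seed = seed)
  res <- data.frame(id = table$markers$id, chrom = table$markers$chrom,
                    pos = table$markers$pos, chi_square = mt$chi_square,
                    p_raw = mt$p_raw, p_genome = mt$p_genome,
                    stringsAsFactors = FALSE)
  structure(list(result = res, lambda = inflation_factor(mt$chi_square),
                 clusters = clusters, k = k_clusters, n_perm = n_perm,
                 seed = seed, bonferroni = 0.05 / nrow(res)),
            class = "assoc_scan")
}

#' @method print assoc_scan
#' @export
print.assoc_scan <- function(x, ...) {
  top <- x$result[which.min(x$result$p_genome), ]
  cat(sprintf("assoc_scan: %d markers, K=%d, %d permutations (seed %d)\n",
              nrow(x$result), x$k, x$n_perm, x$seed))
  cat(sprintf("  lambda = %.3f\n", x$lambda))
  cat(sprintf("  top marker %s (%s:%d): chi2=%.2f p_raw=%.3g p_genome=%.3g\n",
              top$id, top$chrom, top$pos, top$chi_square, top$p_raw,
              top$p_genome))
  invisible(x)
}

#' Write association scan outputs
#' @param scan an `assoc_scan`.
#' @param tsv_path per-marker TSV path.
#' @param json_path summary JSON path (lambda, K, n_perm, seed).
#' @return invisibly, the paths.
#' @export
write_assoc_scan <- function(scan, tsv_path, json_path) {
  utils::write.table(scan$result, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(lambda = scan$lambda, k = scan$k,
                            n_perm = scan$n_perm, seed = scan$seed,
                            bonferroni = scan$bonferroni),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv_path, json = json_path))
}
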