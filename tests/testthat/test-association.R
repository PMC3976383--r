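test_that("identical samples cluster together and K=1 reduces to one cluster", {
  geno <- rbind(c("AA", "AB", "BB", "AA"),
                c("AA", "AB", "BB", "AA"),
                c("BB", "BB", "AA", "AB"),
                c("BB", "BB", "AA", "AB"))
  tab <- gt_from_strings(c("case", "case", "control", "control"), geno)
  d <- ibs_distance(tab)
  expect_equal(d["S01", "S02"], 0)
  cl <- ibs_cluster(tab, 2)
  expect_equal(cl[["S01"]], cl[["S02"]])
  expect_equal(cl[["S03"]], cl[["S04"]])
  expect_false(cl[["S01"]] == cl[["S03"]])
  expect_equal(unname(ibs_cluster(tab, 1)), rep(1L, 4))
})

test_that("IBS clustering recovers two diverged subpopulations", {
  sim <- gen_cohort(cohort_sim_config(n_cases = 20, n_controls = 20,
                                      n_obligate_carriers = 0,
                                      n_markers = 500, locus_homogeneity = 0,
                                      control_carrier_rate = 0,
                                      n_subpopulations = 2, divergence = 0.2,
                                      seed = 9))
  cl <- ibs_cluster(sim$table, 2)
  truth <- sim$table$samples$subpop
  agree <- max(mean(cl == truth), mean(cl == 3 - truth))
  expect_gte(agree, 0.95)
})

test_that("allelic test matches the textbook chi-square and scales correctly", {
  expect_equal(allelic_test(matrix(c(10, 10, 5, 5), 2))$chi_square, 0)
  expect_equal(allelic_test(matrix(c(10, 10, 5, 5), 2))$p_raw, 1)
  tab <- matrix(c(30, 5, 14, 15), 2)
  got <- allelic_test(tab)
  ora <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(got$chi_square, unname(ora$statistic))
  expect_equal(got$p_raw, unname(ora$p.value))
  expect_equal(allelic_test(2 * tab)$chi_square, 2 * got$chi_square)
  expect_error(allelic_test(matrix(0, 2, 2)), "zero total")
})

test_that("CMH reduces to the allelic test with one stratum", {
  set.seed(5)
  for (r in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(cmh_test(tab)$chi_square, allelic_test(tab)$chi_square)
  }
})

test_that("CMH handles confounding, identical strata and skips empty strata", {
  ## Simpson's-paradox fixture: strong marginal association, none within
  ## stratum (case allele fraction equals control fraction in each stratum)
  s1 <- matrix(c(80, 40, 20, 10), 2)                 # cases 80:20, ctrl 40:10
  s2 <- matrix(c(10, 40, 20, 80), 2)                 # cases 10:20, ctrl 40:80
  expect_equal(cmh_test(array(c(s1, s2), c(2, 2, 2)))$chi_square, 0,
               tolerance = 1e-12)
  marginal <- allelic_test(s1 + s2)$chi_square
  expect_gt(marginal, 10)

  ## K identical strata: statistic is K times the single-stratum statistic
  t1 <- matrix(c(30, 12, 10, 25), 2)
  expect_equal(cmh_test(array(rep(t1, 3), c(2, 2, 3)))$chi_square,
               3 * cmh_test(t1)$chi_square)

  ## independent cross-check: classical MH statistic differs from the
  ## n^3-variance form by a per-stratum factor (n-1)/n
  set.seed(8)
  arr <- array(rpois(12, 15) + 1, c(2, 2, 3))
  ours <- cmh_test(arr)$chi_square
  mh <- unname(stats::mantelhaen.test(arr, correct = FALSE)$statistic)
  ns <- apply(arr, 3, sum)
  expect_gte(mh / ours, min((ns - 1) / ns))
  expect_lte(mh / ours, max((ns - 1) / ns))

  expect_warning(cmh_test(array(c(t1, matrix(0, 2, 2)), c(2, 2, 2))),
                 "skipped")
})

test_that("max(T) permutation p-values are smoothed, tied-up and order-invariant", {
  set.seed(31)
  tab <- random_gt(6, 6, m = 12, miss = 0)
  mt <- maxt_permutation(tab, n_perm = 99, seed = 7)
  expect_true(all(mt$p_genome >= 1 / 100))
  expect_true(all(mt$p_genome <= 1))
  ## a null-statistic marker (monomorphic -> chi2 0) gets p_genome 1
  geno <- cbind(rep("AA", 12), matrix("AB", 12, 1))
  tab0 <- gt_from_strings(rep(c("case", "control"), each = 6), geno)
  mt0 <- maxt_permutation(tab0, n_perm = 49, seed = 3)
  expect_equal(mt0$chi_square[1], 0)
  expect_equal(mt0$p_genome[1], 1)
  ## marker order does not change per-marker results
  perm <- sample(ncol(tab$a1))
  tab_perm <- genotype_table(tab$samples, tab$markers[perm, ],
                             tab$a1[, perm], tab$a2[, perm])
  mt2 <- maxt_permutation(tab_perm, n_perm = 99, seed = 7)
  expect_equal(mt2$p_genome, mt$p_genome[perm])
  expect_equal(mt2$chi_square, mt$chi_square[perm])
})

test_that("a fully penetrant recessive locus tops the scan in most replicates", {
  hits <- 0L
  for (r in 1:50) {
    sim <- gen_cohort(cohort_sim_config(n_cases = 20, n_controls = 20,
                                        n_obligate_carriers = 0,
                                        n_markers = 500,
                                        locus_homogeneity = 1,
                                        seed = 1000 + r))
    mt <- maxt_permutation(sim$table, n_perm = 100, seed = 2000 + r)
    if (mt$p_genome[sim$truth$causal_index] == min(mt$p_genome))
      hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.9)
})

test_that("genomic inflation is calibrated and scale-equivariant", {
  set.seed(12)
  expect_equal(inflation_factor(rchisq(10000, df = 1)), 1, tolerance = 0.05)
  expect_equal(inflation_factor(rep(0.4549, 5)), 1, tolerance = 1e-3)
  x <- rchisq(101, df = 1)
  expect_equal(inflation_factor(2 * x), 2 * inflation_factor(x))
  expect_error(inflation_factor(numeric(0)), "no statistics")
})

test_that("assoc_scan ties the stages together deterministically", {
  sim <- gen_cohort(cohort_sim_config(n_cases = 12, n_controls = 12,
                                      n_obligate_carriers = 0,
                                      n_markers = 60, locus_homogeneity = 0,
                                      seed = 77))
  sc1 <- assoc_scan(sim$table, k_clusters = 2, n_perm = 100, seed = 5)
  sc2 <- assoc_scan(sim$table, k_clusters = 2, n_perm = 100, seed = 5)
  expect_equal(sc1$result, sc2$result)
  expect_gt(sc1$lambda, 0)
  expect_equal(sc1$bonferroni, 0.05 / 60)
  tsv <- tempfile(); js <- tempfile()
  write_assoc_scan(sc1, tsv, js)
  expect_equal(nrow(utils::read.delim(tsv)), 60)
  expect_equal(jsonlite::read_json(js)$n_perm, 100L)
})
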