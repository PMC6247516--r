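test_that("multilocus theta matches the literal variance-component oracle", {
  set.seed(701)
  for (rep in 1:20) {
    n <- sample(6:20, 1); L <- sample(1:5, 1)
    gm <- random_gm(n, L, max_allele = sample(2:6, 1), miss = 0.1)
    labels <- sample(rep(c("x", "y"), length.out = n))
    # guard against groups with no data at any locus
    th <- wc_theta(gm, labels, n_boot = 0)$theta
    expect_equal(th, oracle_wc_theta(gm, labels), tolerance = 1e-12)
  }
  # three groups too
  gm <- random_gm(30, 4, miss = 0.05)
  labels <- sample(rep(c("x", "y", "z"), 10))
  expect_equal(wc_theta(gm, labels, n_boot = 0)$theta,
               oracle_wc_theta(gm, labels), tolerance = 1e-12)
})

test_that("theta hits its boundary cases", {
  # groups fixed for different alleles at every locus -> theta = 1
  g1 <- array(1L, c(8, 3, 2)); g2 <- array(2L, c(8, 3, 2))
  gm <- bind_genotypes(genotype_matrix(g1, ids = sprintf("a%d", 1:8)),
                       genotype_matrix(g2, ids = sprintf("b%d", 1:8)))
  expect_equal(wc_theta(gm, rep(1:2, each = 8), n_boot = 0)$theta, 1)
  # two groups drawn from one pool -> theta near 0
  set.seed(702)
  p <- replicate(10, {v <- runif(4); v / sum(v)}, simplify = FALSE)
  big <- simulate_parental_genotypes(p, 2000)
  expect_lt(abs(wc_theta(big, rep(1:2, 1000), n_boot = 0)$theta), 0.01)
  expect_error(wc_theta(big, rep(1, 2000)), "two groups")
})

test_that("bootstrap CI brackets theta and is seeded", {
  set.seed(703)
  cfg <- sim_config(n_per_species = c(A = 80, B = 80))
  ds <- simulate_dataset(cfg, seed = 703)
  f1 <- wc_theta(ds$genotypes, ds$truth$species, n_boot = 200, seed = 1)
  f2 <- wc_theta(ds$genotypes, ds$truth$species, n_boot = 200, seed = 1)
  expect_identical(f1$ci95, f2$ci95)
  expect_lt(f1$ci95[1], f1$theta)
  expect_gt(f1$ci95[2], f1$theta)
})

test_that("locus summaries report Na, Ho, He and Fis per group", {
  # monomorphic locus: Na = 1, Ho = He = 0, Fis undefined
  g <- array(5L, c(6, 1, 2))
  ls <- locus_summaries(genotype_matrix(g), rep("g1", 6))
  expect_equal(ls$table$Na, 1L)
  expect_equal(ls$table$Ho, 0)
  expect_equal(ls$table$He, 0)
  expect_true(is.na(ls$table$Fis))
  # hand-computed 4-individual example: genotypes (1,1) (1,2) (1,2) (2,2)
  # p = 0.5, Ho = 0.5, He (unbiased) = 8/7 * 0.5 = 0.5714...
  arr <- array(c(1L, 1L, 1L, 2L, 1L, 2L, 2L, 2L), dim = c(4, 1, 2))
  ls2 <- locus_summaries(genotype_matrix(arr), rep("g", 4))
  expect_equal(ls2$table$Ho, 0.5)
  expect_equal(ls2$table$He, (8 / 7) * (1 - 2 * 0.25), tolerance = 1e-12)
  # Weir-Cockerham single-sample f by direct formula: b and c components
  n <- 4; hbar <- 0.5; p <- 0.5
  b_u <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
  f_hand <- 1 - (hbar / 2) / (b_u + hbar / 2) # identical for both alleles
  expect_equal(ls2$table$Fis, f_hand, tolerance = 1e-12)
  # invariant under allele relabeling
  set.seed(704)
  gm <- random_gm(20, 3, miss = 0)
  gm2 <- gm; gm2$alleles[] <- gm$alleles * 13L + 4L
  l1 <- locus_summaries(gm, rep(1:2, 10)); l2 <- locus_summaries(gm2, rep(1:2, 10))
  expect_equal(l1$table[, c("Na", "Ho", "He", "Fis")],
               l2$table[, c("Na", "Ho", "He", "Fis")])
  expect_equal(l1$fst_per_locus, l2$fst_per_locus)
})

test_that("rarefied allelic richness interpolates between 1 and Na", {
  set.seed(705)
  gm <- random_gm(40, 4, max_allele = 8, miss = 0)
  ar <- allelic_richness(gm, rep(1:2, 20), g = 10)
  ls <- locus_summaries(gm, rep(1:2, 20))
  na <- matrix(ls$table$Na, ncol = 2, byrow = TRUE)
  expect_true(all(ar >= 1 & ar <= na + 1e-9))
})

test_that("pairwise differentiation combines theta with a permutation G test", {
  set.seed(706)
  # disjointly fixed groups: minimal possible p = 1/(m+1)
  g1 <- array(1L, c(6, 3, 2)); g2 <- array(2L, c(6, 3, 2))
  gm <- bind_genotypes(genotype_matrix(g1, ids = sprintf("a%d", 1:6)),
                       genotype_matrix(g2, ids = sprintf("b%d", 1:6)))
  pf <- pairwise_fst(gm, rep(c("A", "B"), each = 6), n_perm = 99, seed = 1)
  expect_equal(pf$p_value["A", "B"], 1 / 100)
  expect_equal(pf$theta["A", "B"], 1)
  # the G statistic equals the hand-computed log-likelihood ratio on the
  # pooled allele-count table: 2 * sum O * ln(O/E)
  cnts <- function(x) tabulate(x, 2)
  o <- rbind(c(12, 0), c(0, 12))  # allele counts per group at one locus
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  g_hand <- 2 * sum(o[o > 0] * log(o[o > 0] / e[o > 0])) * 3  # 3 loci
  # recompute via the package internals
  ec <- cryptohyb:::encode_alleles(gm)
  al <- cryptohyb:::allele_id_lists(ec)
  cA <- tabulate(unlist(al$ids[1:6]), al$M)
  cB <- tabulate(unlist(al$ids[7:12]), al$M)
  expect_equal(cryptohyb:::g_stat_counts(cA, cB, al$locus_of), g_hand)
  # duplicated identical groups: theta near zero, p not extreme
  set.seed(707)
  base <- random_gm(15, 4, miss = 0)
  dup <- bind_genotypes(base, base)
  pf2 <- pairwise_fst(dup, rep(1:2, each = 15), n_perm = 99, seed = 2)
  expect_lt(abs(pf2$theta[1, 2]), 0.05)
  expect_gt(pf2$p_value[1, 2], 0.05)
})

test_that("HWE permutation test flags extreme heterozygote deficit", {
  # 50 homozygotes at a two-allele locus with p = q = 0.5
  arr <- array(c(rep(1L, 25), rep(2L, 25)), dim = c(50, 1, 2))
  gm <- genotype_matrix(array(rep(arr, 1), dim = c(50, 1, 2)))
  ht <- hwe_test(gm, rep("g", 50), n_perm = 2000, seed = 708)
  expect_lt(ht$p, 0.001)
  expect_gt(ht$f, 0.9)
  # monomorphic locus is NA
  ht2 <- hwe_test(genotype_matrix(array(1L, c(10, 1, 2))), rep("g", 10),
                  n_perm = 100)
  expect_true(is.na(ht2$p))
})

test_that("HWE test keeps its nominal type-I error under equilibrium", {
  set.seed(709)
  n_tests <- 300
  p_vals <- replicate(n_tests, {
    alle <- sample(1:4, 120, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    arr <- array(alle, dim = c(60, 1, 2))
    hwe_test(genotype_matrix(arr), rep("g", 60), n_perm = 400)$p
  })
  rate <- mean(p_vals < 0.05)
  # binomial tolerance around the nominal 5% level
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / n_tests))
})

test_that("linkage test detects a duplicated locus and not independent ones", {
  set.seed(710)
  x1 <- sample(1:3, 20, TRUE); x2 <- sample(1:3, 20, TRUE)
  y1 <- sample(1:3, 20, TRUE); y2 <- sample(1:3, 20, TRUE)
  arr <- array(c(x1, x1, y1, x2, x2, y2), dim = c(20, 3, 2))
  gm <- genotype_matrix(arr)  # locus 2 duplicates locus 1; locus 3 independent
  lt <- ld_test(gm, rep("g", 20), n_perm = 199, seed = 710)
  p12 <- lt$p[lt$locus1 == "locus_01" & lt$locus2 == "locus_02"]
  expect_equal(p12, 1 / 200)
  p13 <- lt$p[lt$locus1 == "locus_01" & lt$locus2 == "locus_03"]
  expect_gt(p13, 0.05)
})

test_that("null-allele estimators follow their defining formulas", {
  # Ho = He exactly -> estimate 0; Ho = 0 -> Chakraborty estimate 1
  set.seed(711)
  arr <- array(c(rep(1L, 10), rep(2L, 10)), dim = c(20, 1, 2))  # all hom
  gm <- genotype_matrix(arr)
  ns <- null_allele_scan(gm, rep("g", 20))
  expect_equal(ns$Ho, 0)
  expect_equal(ns$null_freq, 1)
  expect_lt(ns$p, 0.01)
  # Brookfield variant
  nb <- null_allele_scan(gm, rep("g", 20), estimator = "brookfield1")
  expect_equal(nb$null_freq, ns$He / (1 + ns$He))
  # a locus simulated in equilibrium is not significant (usually)
  big <- simulate_parental_genotypes(list(c(0.5, 0.3, 0.2)), 500)
  nf <- null_allele_scan(big, rep("g", 500))
  expect_lt(abs(nf$null_freq), 0.15)
})

test_that("sex-biased dispersal statistic is zero for mirrored sexes", {
  set.seed(712)
  base <- random_gm(40, 5, miss = 0)
  gm <- bind_genotypes(base, base)  # females and males identical
  sex <- rep(c("F", "M"), each = 40)
  site <- rep(rep(c("s1", "s2"), each = 20), 2)
  r <- sex_biased_dispersal_test(gm, sex, site, "male", n_rand = 99, seed = 1)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_gt(r$p_value, 0.05)
  expect_true(r$p_value > 0 && r$p_value <= 1)
})

test_that("dispersal test keeps its level without spatial structure", {
  set.seed(713)
  p_vals <- replicate(25, {
    gm <- random_gm(60, 5, miss = 0)
    sex <- sample(rep(c("F", "M"), 30))
    site <- sample(rep(c("s1", "s2", "s3"), 20))
    sex_biased_dispersal_test(gm, sex, site, "male", n_rand = 60)$p_value
  })
  expect_gt(mean(p_vals > 0.05), 0.75)
})
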