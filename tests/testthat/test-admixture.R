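tiny_mcmc <- function(K = 2, seed = NULL)
  mcmc_config(K = K, burn_in = 2000, length = 6000, thin = 10, seed = seed)

test_that("K = 1 gives degenerate ancestry and a finite evidence estimate", {
  set.seed(601)
  gm <- random_gm(10, 4)
  r <- run_admixture(gm, tiny_mcmc(K = 1, seed = 601))
  expect_true(all(r$q_mean == 1))
  expect_true(is.finite(r$lnPD))
})

test_that("disjointly fixed populations are recovered almost exactly", {
  g1 <- array(1L, c(10, 5, 2)); g2 <- array(2L, c(10, 5, 2))
  gm <- bind_genotypes(genotype_matrix(g1, ids = sprintf("a%d", 1:10)),
                       genotype_matrix(g2, ids = sprintf("b%d", 1:10)))
  r <- run_admixture(gm, tiny_mcmc(seed = 602))
  # posterior concentrates on the generating labels
  own <- pmax(r$q_mean[, 1], r$q_mean[, 2])
  expect_gt(min(own), 0.98)
  expect_equal(max(abs(r$q_mean[1:10, ] - r$q_mean[rep(1, 10), ])), 0,
               tolerance = 0.02)
  # credibility bounds bracket the means
  expect_true(all(r$q_ci90_lower <= r$q_mean + 1e-9))
  expect_true(all(r$q_ci90_upper >= r$q_mean - 1e-9))
})

test_that("rows of q sum to one and lnPD matches its defining formula", {
  set.seed(603)
  gm <- random_gm(15, 5)
  r <- run_admixture(gm, tiny_mcmc(seed = 603))
  expect_equal(unname(rowSums(r$q_mean)), rep(1, 15), tolerance = 1e-9)
  expect_equal(r$lnPD,
               mean(r$loglik_trace) - stats::var(r$loglik_trace) / 2)
})

test_that("with no data the ancestry posterior equals its Dirichlet prior", {
  # detailed-balance smoke test: all genotypes missing -> q_i ~ Dir(alpha)
  arr <- array(-9L, dim = c(12, 4, 2))
  gm_all <- genotype_matrix(arr, ids = sprintf("m%d", 1:12))
  r <- run_admixture(gm_all, tiny_mcmc(seed = 604))
  # symmetric Dirichlet: mean 1/2 per cluster
  expect_equal(unname(colMeans(r$q_mean)), c(0.5, 0.5), tolerance = 0.05)
  expect_equal(unname(r$q_mean[1, 1]), 0.5, tolerance = 0.05)
})

test_that("permuting individuals permutes the q rows identically", {
  set.seed(605)
  gm <- random_gm(12, 5, miss = 0)
  perm <- sample(12)
  r1 <- run_admixture(gm, tiny_mcmc(seed = 605))
  r2 <- run_admixture(subset_genotypes(gm, perm), tiny_mcmc(seed = 605))
  # align labels before comparing (runs label clusters arbitrarily)
  cons <- align_runs(list(r1))
  p <- cryptohyb:::match_columns(r2$q_mean[order(perm), , drop = FALSE], r1$q_mean)
  expect_equal(unname(r2$q_mean[order(perm), p]), unname(r1$q_mean),
               tolerance = 0.1)
})

test_that("small two-deme instances keep deme-mates together", {
  # two demes fixed for different alleles: members of a deme share their
  # majority cluster and the two demes take opposite clusters (on very
  # small instances the within-chain label symmetry flattens the marginal
  # q, so the check is on co-assignment, not on q itself)
  g1 <- array(1L, c(6, 4, 2)); g2 <- array(2L, c(6, 4, 2))
  gm <- bind_genotypes(genotype_matrix(g1, ids = sprintf("a%d", 1:6)),
                       genotype_matrix(g2, ids = sprintf("b%d", 1:6)))
  r <- run_admixture(gm, mcmc_config(K = 2, burn_in = 4000, length = 20000,
                                     thin = 10, seed = 606))
  expect_gt(max(r$q_mean[1, ]), 0.8)
  expect_equal(length(unique(apply(r$q_mean[1:6, ], 1, which.max))), 1L)
  expect_equal(length(unique(apply(r$q_mean[7:12, ], 1, which.max))), 1L)
  expect_true(which.max(r$q_mean[1, ]) != which.max(r$q_mean[7, ]))
})

test_that("run alignment undoes label switching and averages runs", {
  set.seed(607)
  q <- matrix(runif(20), 10, 2); q <- q / rowSums(q)
  mk_run <- function(qm, lnpd) structure(
    list(q_mean = qm, q_ci90_lower = pmax(qm - 0.1, 0),
         q_ci90_upper = pmin(qm + 0.1, 1), lnPD = lnpd,
         ids = sprintf("i%d", 1:10), K = 2L), class = "admixture_run")
  r1 <- mk_run(q, -100)
  r2 <- mk_run(q[, 2:1], -101)      # identical up to a column swap
  cons <- align_runs(list(r1, r2))
  expect_equal(cons$q, q, tolerance = 1e-12)
  # single run: consensus equals the run
  expect_equal(align_runs(list(r1))$q, q)
  # consensus is the mean of the aligned q matrices (exact permutation
  # search over all K! column orders for K <= 3)
  q3 <- matrix(runif(30), 10, 3); q3 <- q3 / rowSums(q3)
  perms <- cryptohyb:::all_permutations(3)
  r3a <- structure(list(q_mean = q3, q_ci90_lower = q3, q_ci90_upper = q3,
                        lnPD = -1, ids = sprintf("i%d", 1:10), K = 3L),
                   class = "admixture_run")
  for (j in seq_len(nrow(perms))) {
    qp <- q3[, perms[j, ]]
    r3b <- structure(list(q_mean = qp, q_ci90_lower = qp, q_ci90_upper = qp,
                          lnPD = -2, ids = sprintf("i%d", 1:10), K = 3L),
                     class = "admixture_run")
    cons3 <- align_runs(list(r3a, r3b))
    expect_equal(cons3$q, q3, tolerance = 1e-12)
  }
  expect_error(align_runs(list(r1, r3a)), "differ in K")
})

test_that("Evanno delta-K is the standardized second difference", {
  # hand calculation: lnPD means (-100, -50, -49, -48.5), sd 1 at each K
  # deltaK(2) = |(-49) - 2(-50) + (-100)| / 1 = 49
  # deltaK(3) = |(-48.5) - 2(-49) + (-50)| / 1 = 0.5
  base <- c(-100, -50, -49, -48.5)
  lnpd <- rbind(base + 1, base - 1)  # sd = sqrt(2), means = base
  colnames(lnpd) <- 1:4
  et <- evanno_deltaK(lnpd)
  expect_equal(et$deltaK, c(NA, 49, 0.5, NA) / sd(c(1, -1)))
  expect_equal(attr(et, "best_K"), 2L)
  # linear lnPD in K: all interior deltaK exactly 0
  lin <- rbind(c(-10, -8, -6, -4) + 0.5, c(-10, -8, -6, -4) - 0.5)
  colnames(lin) <- 1:4
  expect_equal(evanno_deltaK(lin)$deltaK, c(NA, 0, 0, NA))
  # zero sd -> undefined, not infinite
  flat <- rbind(base, base); colnames(flat) <- 1:4
  expect_true(all(is.na(evanno_deltaK(flat)$deltaK)))
  expect_error(evanno_deltaK(lnpd[, 1:2]), "at least 3")
})

test_that("cluster assignment breaks ties toward the lowest index", {
  cons <- fake_consensus(rbind(c(0.9, 0.1), c(0.5, 0.5)))
  a <- assign_clusters(cons)
  expect_equal(a$cluster, c(1L, 1L))
  expect_equal(a$tie, c(FALSE, TRUE))
})
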