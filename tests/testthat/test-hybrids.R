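fixed_pool <- function(allele, n = 10, L = 4, ids = NULL)
  genotype_matrix(array(allele, c(n, L, 2)), ids = ids)

test_that("reference parents are the highest-q individuals per cluster", {
  q <- rbind(c(0.99, 0.01), c(0.95, 0.05), c(0.90, 0.10),
             c(0.05, 0.95), c(0.02, 0.98))
  cons <- fake_consensus(q, ids = c("c", "a", "b", "d", "e"))
  sel <- select_reference_parents(cons, n = 1)
  expect_equal(sel$cluster1, "c")
  expect_equal(sel$cluster2, "e")
  # ties broken lexicographically by id
  qt <- matrix(rep(c(1, 0), each = 5), 5)
  const <- fake_consensus(qt, ids = c("e", "b", "a", "d", "c"))
  # cluster 2 is empty here, which itself warns; the tie-break is on cluster 1
  expect_equal(suppressWarnings(select_reference_parents(const, n = 3))$cluster1,
               c("a", "b", "c"))
  # n = 3: cluster 1 has exactly 3 members, cluster 2 only 2 -> one warning
  expect_warning(select_reference_parents(cons, n = 3), "only")
})

test_that("hybrid classes follow gamete semantics", {
  pa <- fixed_pool(1L, ids = sprintf("pa%d", 1:10))
  pb <- fixed_pool(2L, ids = sprintf("pb%d", 1:10))
  cfg <- hybrid_sim_config(class_counts = c(parental_A = 5, parental_B = 5,
                                            F1 = 20, F2 = 0, BC_A = 0, BC_B = 0))
  sim <- simulate_hybrid_classes(pa, pb, cfg, seed = 801)
  f1 <- sim$genotypes$alleles[sim$classes == "F1", , , drop = FALSE]
  # every F1 genotype is the (a, b) heterozygote at every locus
  expect_true(all(sort(unique(as.vector(f1[, , 1]))) == 1))
  expect_true(all(sort(unique(as.vector(f1[, , 2]))) == 2))
  parA <- sim$genotypes$alleles[sim$classes == "parental_A", , , drop = FALSE]
  expect_true(all(parA == 1L))
  # no missing data among simulants
  expect_false(any(sim$genotypes$alleles == -9L))
})

test_that("backcrosses carry three quarters of the recurrent pool's alleles", {
  pa <- fixed_pool(1L); pb <- fixed_pool(2L)
  cfg <- hybrid_sim_config(class_counts = c(BC_A = 4000))
  sim <- simulate_hybrid_classes(pa, pb, cfg, seed = 802)
  frac_a <- mean(sim$genotypes$alleles == 1L)
  expect_lt(abs(frac_a - 0.75),
            4 * sqrt(0.75 * 0.25 / (4000 * 4 * 2)))
})

test_that("degenerate simulation inputs are rejected or empty", {
  pa <- fixed_pool(1L); pb <- fixed_pool(2L)
  empty <- simulate_hybrid_classes(
    pa, pb, hybrid_sim_config(class_counts = c(F1 = 0)))
  expect_equal(length(empty$classes), 0L)
  # a locus with no amplified genotypes in a pool is an error naming it
  bad <- pa; bad$alleles[, 2, ] <- -9L
  expect_error(simulate_hybrid_classes(bad, pb, hybrid_sim_config()),
               "locus_02")
  pc <- fixed_pool(1L, L = 3)
  expect_error(simulate_hybrid_classes(pa, pc, hybrid_sim_config()),
               "same loci")
})

test_that("thresholds are the minimum simulated-parental q per cluster", {
  cls <- c(rep("parental_A", 4), rep("parental_B", 4))
  q <- rbind(c(0.99, 0.01), c(0.95, 0.05), c(0.97, 0.03), c(0.96, 0.04),
             c(0.05, 0.95), c(0.24, 0.76), c(0.03, 0.97), c(0.02, 0.98))
  ids <- sprintf("s%d", 1:8)
  sim <- list(classes = cls, genotypes = list(ids = ids))
  cons <- fake_consensus(q, ids = ids)
  tp <- calibrate_thresholds(sim, cons)
  expect_equal(tp$TP1, 0.95)
  expect_equal(tp$TP2, 0.76)
  expect_equal(tp$cluster_A, 1L)
  # thresholds are non-increasing as more parental simulants are added
  for (extra in seq(0.9, 0.99, by = 0.03)) {
    sim2 <- list(classes = c(cls, "parental_A"),
                 genotypes = list(ids = c(ids, "x")))
    cons2 <- fake_consensus(rbind(q, c(extra, 1 - extra)),
                            ids = c(ids, "x"))
    expect_lte(calibrate_thresholds(sim2, cons2)$TP1, tp$TP1)
  }
  sim3 <- list(classes = rep("F1", 8), genotypes = list(ids = ids))
  expect_error(calibrate_thresholds(sim3, cons), "no parental")
})

test_that("classification applies the stated conservative and relaxed rules", {
  tp <- list(TP1 = 0.90, TP2 = 0.76, cluster_A = 1L, cluster_B = 2L)
  q <- rbind(c(0.95, 0.05), c(1.0, 0.0), c(0.5, 0.5), c(0.10, 0.90))
  lo <- rbind(c(0.80, 0.0), c(1.0, 0.9), c(0.4, 0.4), c(0.05, 0.80))
  cons <- fake_consensus(q, ci_lower = lo)
  hc <- classify_hybrids(cons, tp)
  # mean q over threshold but CI lower bound under it: conservative parent,
  # relaxed hybrid
  expect_equal(hc$conservative[1], "parent_1")
  expect_equal(hc$relaxed[1], "hybrid")
  expect_equal(hc$conservative[2], "parent_1")
  expect_equal(hc$relaxed[2], "parent_1")
  expect_equal(hc$conservative[3], "hybrid")
  expect_equal(hc$relaxed[3], "hybrid")
  expect_equal(hc$conservative[4], "parent_2")
  expect_equal(hc$relaxed[4], "parent_2")
})

test_that("conservative hybrids are always relaxed hybrids and labels are
           invariant to cluster relabeling", {
  set.seed(803)
  for (rep in 1:20) {
    q1 <- runif(10)
    q <- cbind(q1, 1 - q1)
    lo <- pmax(q - matrix(runif(20, 0, 0.3), 10), 0)
    cons <- fake_consensus(q, ci_lower = lo)
    tp <- list(TP1 = runif(1, 0.7, 0.99), TP2 = runif(1, 0.7, 0.99),
               cluster_A = 1L, cluster_B = 2L)
    hc <- classify_hybrids(cons, tp)
    expect_true(all(hc$relaxed[hc$conservative == "hybrid"] == "hybrid"))
    # swap q columns and thresholds together
    cons_sw <- fake_consensus(q[, 2:1], ci_lower = lo[, 2:1])
    tp_sw <- list(TP1 = tp$TP1, TP2 = tp$TP2, cluster_A = 2L, cluster_B = 1L)
    hc_sw <- classify_hybrids(cons_sw, tp_sw)
    expect_equal(hc$conservative == "hybrid", hc_sw$conservative == "hybrid")
    expect_equal(hc$relaxed == "hybrid", hc_sw$relaxed == "hybrid")
  }
})

test_that("the relaxed rule flags F1s at least as often as parents", {
  set.seed(805)
  cfg <- sim_config(n_per_species = c(A = 60, B = 60), n_loci = 10)
  fr <- draw_allele_frequencies(cfg)
  pa <- simulate_parental_genotypes(fr$species$A, 60,
                                    ids = sprintf("pa%02d", 1:60))
  pb <- simulate_parental_genotypes(fr$species$B, 60,
                                    ids = sprintf("pb%02d", 1:60))
  sim <- simulate_hybrid_classes(
    pa, pb, hybrid_sim_config(class_counts = c(parental_A = 80,
                                               parental_B = 80, F1 = 60)),
    seed = 806)
  cons <- align_runs(list(run_admixture(
    sim$genotypes, mcmc_config(K = 2, burn_in = 2000, length = 8000,
                               thin = 10, seed = 807))))
  tp <- calibrate_thresholds(sim, cons)
  hc <- classify_hybrids(cons, tp)
  is_f1 <- sim$classes == "F1"
  rate_f1 <- mean(hc$relaxed[match(sim$genotypes$ids[is_f1],
                                   hc$individual_id)] == "hybrid")
  rate_par <- mean(hc$relaxed[match(sim$genotypes$ids[!is_f1],
                                    hc$individual_id)] == "hybrid")
  expect_gte(rate_f1, rate_par)
  expect_gt(rate_f1, 0.5)   # F1s at this differentiation mostly show cues
})

test_that("perfectly separated pools yield a null misclassification rate", {
  pa <- fixed_pool(1L, n = 20, L = 5, ids = sprintf("pa%d", 1:20))
  pb <- fixed_pool(2L, n = 20, L = 5, ids = sprintf("pb%d", 1:20))
  tp <- list(TP1 = 0.9, TP2 = 0.9, cluster_A = 1L, cluster_B = 2L)
  m <- misclassification_study(
    pa, pb, tp, class_counts = c(parental_A = 30, parental_B = 30, F1 = 5,
                                 BC_A = 5, BC_B = 5),
    n_replicates = 2,
    mcmc = mcmc_config(K = 2, burn_in = 2000, length = 6000, thin = 10),
    seed = 804)
  expect_equal(m$rate_conservative, 0)
  expect_equal(m$rate_relaxed, 0)
  expect_equal(nrow(m$replicates), 2L)
  expect_equal(m$replicates$n_parental, c(60L, 60L))
})
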