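test_that("raw distances count differing sites with pairwise deletion", {
  s <- aligned_seqs(c("a", "b", "c"), c("ACGT", "ACGA", "AC-T"))
  dm <- raw_distance(s)
  expect_equal(dm$d["a", "a"], 0)
  expect_equal(dm$d["a", "b"], 0.25)          # one of four sites
  expect_equal(dm$d["a", "c"], 0)             # gap deleted pairwise
  expect_equal(dm$sites_used["a", "c"], 3)
  expect_equal(dm$d, t(dm$d))
  # Ns excluded like gaps
  s2 <- aligned_seqs(c("x", "y"), c("ANGT", "ACGA"))
  expect_equal(raw_distance(s2)$d["x", "y"], 1 / 3)
  expect_warning(
    dz <- raw_distance(aligned_seqs(c("p", "q"), c("NNNN", "ACGT"))),
    "no comparable")
  expect_true(is.na(dz$d["p", "q"]))
})

test_that("raw distances match the brute-force site comparison exactly", {
  set.seed(901)
  for (rep in 1:5) {
    n <- 8
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T", "N", "-"), 60, TRUE,
                   prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = ""),
      character(1))
    al <- aligned_seqs(sprintf("s%d", 1:n), seqs)
    dm <- raw_distance(al)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      expect_identical(dm$d[i, j], oracle_raw_dist(seqs[i], seqs[j]))
    }
    # order invariance
    perm <- sample(n)
    dm2 <- raw_distance(aligned_seqs(al$ids[perm], seqs[perm]))
    expect_equal(dm2$d[al$ids, al$ids], dm$d)
  }
})

test_that("haplogroup partition is single linkage at the cutoff", {
  ds <- simulate_dataset(sim_config(), seed = 902)
  dm <- raw_distance(ds$sequences)
  hp <- haplogroup_partition(dm, 0.02)
  expect_equal(max(hp$groups), 2L)
  # groups coincide with the true mitochondrial haplogroups
  truth_mt <- ds$truth$mt_haplogroup[match(names(hp$groups),
                                           ds$truth$individual_id)]
  expect_equal(length(unique(hp$groups[truth_mt == "A"])), 1L)
  expect_equal(length(unique(hp$groups[truth_mt == "B"])), 1L)
  expect_gt(hp$between_mean, max(hp$within_means) * 3)
  # identical sequences collapse into one group with zero divergence
  same <- aligned_seqs(c("u", "v"), c("ACGT", "ACGT"))
  hp1 <- haplogroup_partition(raw_distance(same), 0.02)
  expect_equal(max(hp1$groups), 1L)
  expect_equal(hp1$within_means, 0)
  expect_error(haplogroup_partition(dm, 1.5), "cutoff")
})

test_that("lowering the cutoff never merges groups", {
  ds <- simulate_dataset(sim_config(), seed = 903)
  dm <- raw_distance(ds$sequences)
  n_groups <- vapply(c(0.10, 0.03, 0.01, 0.003),
                     function(ct) max(haplogroup_partition(dm, ct)$groups),
                     numeric(1))
  expect_true(all(diff(n_groups) >= 0))
})

test_that("discordance table counts cyto-nuclear mismatches by direction", {
  # the study pattern: 38 A-nuclear of which 6 carry B mitochondria, all 42
  # B-nuclear concordant
  nuc <- setNames(rep(c("A", "B"), c(38, 42)), sprintf("i%02d", 1:80))
  mt <- nuc; mt[1:6] <- "B"
  dt <- cytonuclear_discordance(nuc, mt)
  expect_equal(unname(dt$counts["A", "B"]), 6)
  expect_equal(unname(dt$counts["B", "A"]), 0)
  expect_equal(unname(dt$proportions["A"]), 6 / 38)
  expect_true(dt$asymmetric)
  expect_equal(dt$n, 80L)
  expect_equal(sum(dt$counts), 80)
  # marginals equal the label counts
  expect_equal(unname(rowSums(dt$counts)), c(38, 42))
  # fully concordant labels: no asymmetry flag
  dt2 <- cytonuclear_discordance(nuc, nuc)
  expect_equal(sum(dt2$counts) - sum(diag(dt2$counts)), 0)
  expect_false(dt2$asymmetric)
  expect_error(cytonuclear_discordance(setNames("A", "x"), setNames("A", "y")),
               "share no ids")
})

test_that("generator discordance recovers the introgression probability", {
  set.seed(904)
  props <- vapply(1:8, function(i) {
    ds <- simulate_dataset(sim_config(), seed = 9000 + i)
    nuc <- setNames(ds$truth$species, ds$truth$individual_id)
    mt <- setNames(ds$truth$mt_haplogroup, ds$truth$individual_id)
    cytonuclear_discordance(nuc[!is.na(nuc)], mt[!is.na(nuc)])$proportions["A"]
  }, numeric(1))
  # binomial check of the pooled proportion against the configured 0.158
  pool_n <- 8 * 325
  expect_lt(abs(mean(props) - 0.158), 4 * sqrt(0.158 * 0.842 / pool_n))
})
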