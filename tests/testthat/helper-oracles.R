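# Independent oracles used across the test files. These are deliberately
# written as literal, loop-based transcriptions of the published formulas,
# sharing no code with the package implementations they check.

# Weir & Cockerham (1984) multilocus theta: per-allele variance components
# a, b, c computed with explicit loops over populations and alleles.
oracle_wc_theta <- function(gm, labels) {
  groups <- sort(unique(labels))
  sum_a <- 0; sum_abc <- 0
  for (l in seq_along(gm$loci)) {
    a1 <- gm$alleles[, l, 1]; a2 <- gm$alleles[, l, 2]
    present <- a1 != gm$missing_code
    alleles <- sort(unique(c(a1[present], a2[present])))
    # population sample sizes at this locus
    pops <- list()
    for (g in groups) {
      sel <- labels == g & present
      if (sum(sel) >= 1) pops[[length(pops) + 1]] <- which(sel)
    }
    r <- length(pops)
    if (r < 2) next
    n_i <- sapply(pops, length)
    n_bar <- mean(n_i)
    if (n_bar <= 1) next
    n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
    for (u in alleles) {
      p_i <- numeric(r); h_i <- numeric(r)
      for (k in seq_len(r)) {
        idx <- pops[[k]]
        p_i[k] <- sum((a1[idx] == u) + (a2[idx] == u)) / (2 * n_i[k])
        h_i[k] <- sum((a1[idx] == u) != (a2[idx] == u)) / n_i[k]
      }
      p_bar <- sum(n_i * p_i) / (r * n_bar)
      s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
      h_bar <- sum(n_i * h_i) / (r * n_bar)
      a <- (n_bar / n_c) *
        (s2 - (1 / (n_bar - 1)) *
           (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
      b <- (n_bar / (n_bar - 1)) *
        (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
           ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
      cc <- h_bar / 2
      sum_a <- sum_a + a
      sum_abc <- sum_abc + a + b + cc
    }
  }
  sum_a / sum_abc
}

# per-site brute-force raw distance between two sequences
oracle_raw_dist <- function(s1, s2) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  good <- c1 %in% c("A", "C", "G", "T") & c2 %in% c("A", "C", "G", "T")
  if (!any(good)) return(NA_real_)
  sum(c1[good] != c2[good]) / sum(good)
}

# random genotype matrix with missingness, for fuzzed round-trips and the
# theta oracle comparisons
random_gm <- function(n, L, max_allele = 6, miss = 0.1) {
  g1 <- matrix(sample.int(max_allele, n * L, replace = TRUE), n, L)
  g2 <- matrix(sample.int(max_allele, n * L, replace = TRUE), n, L)
  m <- matrix(runif(n * L) < miss, n, L)
  g1[m] <- -9L; g2[m] <- -9L
  genotype_matrix(array(c(g1, g2), dim = c(n, L, 2L)))
}

# minimal consensus_assignment builder for classifier tests
fake_consensus <- function(q, ci_lower = NULL, ci_upper = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(nrow(q)))
  if (is.null(ci_lower)) ci_lower <- pmax(q - 0.05, 0)
  if (is.null(ci_upper)) ci_upper <- pmin(q + 0.05, 1)
  structure(list(q = q, ci90_lower = ci_lower, ci90_upper = ci_upper,
                 n_runs = 1L, permutations = list(seq_len(ncol(q))),
                 ids = ids, K = ncol(q)),
            class = "consensus_assignment")
}
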