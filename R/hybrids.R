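# Simulation-calibrated hybrid classification: simulate hybrid classes from
# reference parents, calibrate q thresholds on the simulated parents, and
# classify real individuals by their consensus q (conservative) or the lower
# bound of its 90% credibility interval (relaxed).

#' Hybrid-simulation configuration
#'
#' @param n_reference_parents individuals with the highest q selected per
#'   cluster as the reference parental pools.
#' @param class_counts named counts of simulants per class
#'   (`parental_A`, `parental_B`, `F1`, `F2`, `BC_A`, `BC_B`).
#' @param n_replicates replicates of the misclassification study.
#' @param seed optional seed.
#' @return A `hybrid_sim_config` list.
#' @export
hybrid_sim_config <- function(n_reference_parents = 80,
                              class_counts = c(parental_A = 300, parental_B = 300,
                                               F1 = 300, F2 = 300,
                                               BC_A = 300, BC_B = 300),
                              n_replicates = 30, seed = NULL) {
  ck <- c("parental_A", "parental_B", "F1", "F2", "BC_A", "BC_B")
  stopifnot(all(names(class_counts) %in% ck), all(class_counts >= 0),
            n_reference_parents >= 1)
  cc <- stats::setNames(rep(0L, length(ck)), ck)
  cc[names(class_counts)] <- as.integer(class_counts)
  structure(list(n_reference_parents = as.integer(n_reference_parents),
                 class_counts = cc, n_replicates = as.integer(n_replicates),
                 seed = seed),
            class = "hybrid_sim_config")
}

#' Class counts used by the misclassification study
#'
#' A scenario with far fewer hybrids than parental forms: 300 simulants per
#' parental class, 10 F1 and 15 backcrosses to each parental form.
#'
#' @return Named integer vector of class counts.
#' @export
misclassification_class_counts <- function() {
  c(parental_A = 300L, parental_B = 300L, F1 = 10L, F2 = 0L,
    BC_A = 15L, BC_B = 15L)
}

#' Select reference parental individuals per cluster
#'
#' The `n` individuals with the highest consensus q in each of the two
#' clusters; ties are broken by id order, so the selection is deterministic.
#'
#' @param consensus a K = 2 [align_runs()] consensus.
#' @param n individuals per cluster (all are taken, with a warning, if a
#'   cluster is smaller).
#' @return List with `cluster1` and `cluster2` id vectors.
#' @export
select_reference_parents <- function(consensus, n = 80) {
  stopifnot(inherits(consensus, "consensus_assignment"))
  if (consensus$K != 2L) stop("reference-parent selection requires K = 2")
  asg <- assign_clusters(consensus)
  sel <- lapply(1:2, function(k) {
    ids <- asg$individual_id[asg$cluster == k]
    qk <- consensus$q[match(ids, consensus$ids), k]
    if (length(ids) < n)
      warning(sprintf("cluster %d has only %d members (< %d); taking all",
                      k, length(ids), n))
    ids[order(-qk, ids)][seq_len(min(n, length(ids)))]
  })
  names(sel) <- c("cluster1", "cluster2")
  sel
}

pool_freqs <- function(gm) {
  ec <- encode_alleles(gm)
  lapply(seq_along(gm$loci), function(l) {
    a <- c(ec$enc[, 2L * l - 1L], ec$enc[, 2L * l])
    a <- a[a > 0L]
    if (length(a) == 0L)
      stop("locus '", gm$loci[l], "' has no amplified genotypes in a parental pool")
    cnt <- tabulate(a, nbins = ec$n_alleles[l])
    stats::setNames(cnt / sum(cnt), ec$levels[[l]])
  })
}

decode_freq_gametes <- function(freqs, n) {
  # draws allele *codes* (names of the frequency vectors)
  vapply(freqs, function(p) {
    as.integer(names(p))[sample.int(length(p), n, replace = TRUE, prob = p)]
  }, integer(n))
}

#' Simulate hybrid classes from two parental pools
#'
#' Gamete semantics (the `hybridize` convention): a parental-class simulant
#' draws both alleles per locus from its pool's empirical allele
#' frequencies; an F1 draws one allele from each pool; an F2 is the union of
#' two independent F1 gametes; a backcross BC_X is an F1 gamete plus a
#' gamete of pool X. Simulants carry no missing data.
#'
#' @param parents_a,parents_b [genotype_matrix()] pools with identical loci.
#' @param cfg a [hybrid_sim_config()] (its `class_counts` are used).
#' @param seed optional seed.
#' @return List: `genotypes` ([genotype_matrix()]), `classes` (character
#'   vector of class labels per simulant).
#' @export
simulate_hybrid_classes <- function(parents_a, parents_b,
                                    cfg = hybrid_sim_config(), seed = NULL) {
  stopifnot(inherits(parents_a, "genotype_matrix"),
            inherits(parents_b, "genotype_matrix"))
  if (!identical(parents_a$loci, parents_b$loci))
    stop("parental pools must share the same loci")
  if (!is.null(seed)) set.seed(seed)
  cc <- cfg$class_counts
  fA <- pool_freqs(parents_a); fB <- pool_freqs(parents_b)
  L <- length(parents_a$loci)
  n_tot <- sum(cc)
  if (n_tot == 0L) {
    return(list(genotypes = NULL, classes = character(0)))
  }
  f1g <- function(n) {
    a <- decode_freq_gametes(fA, n); b <- decode_freq_gametes(fB, n)
    pick <- matrix(stats::runif(n * L) < 0.5, n, L)
    ifelse(pick, a, b)
  }
  gam_pair <- function(cls, n) {
    switch(cls,
      parental_A = list(decode_freq_gametes(fA, n), decode_freq_gametes(fA, n)),
      parental_B = list(decode_freq_gametes(fB, n), decode_freq_gametes(fB, n)),
      F1 = list(decode_freq_gametes(fA, n), decode_freq_gametes(fB, n)),
      F2 = list(f1g(n), f1g(n)),
      BC_A = list(f1g(n), decode_freq_gametes(fA, n)),
      BC_B = list(f1g(n), decode_freq_gametes(fB, n)))
  }
  g1 <- matrix(0L, n_tot, L); g2 <- matrix(0L, n_tot, L)
  classes <- character(n_tot)
  at <- 0L
  for (cls in names(cc)) {
    n <- cc[[cls]]
    if (n == 0L) next
    gp <- gam_pair(cls, n)
    rows <- at + seq_len(n)
    g1[rows, ] <- matrix(gp[[1]], n, L); g2[rows, ] <- matrix(gp[[2]], n, L)
    classes[rows] <- cls
    at <- at + n
  }
  gm <- genotype_matrix(array(c(g1, g2), dim = c(n_tot, L, 2L)),
                        ids = sprintf("sim_%s_%04d", classes, seq_len(n_tot)),
                        loci = parents_a$loci)
  list(genotypes = gm, classes = classes)
}

#' Calibrate hybrid-detection thresholds from simulated parents
#'
#' TP1 and TP2 are the lowest q-values reached by a simulated parent in its
#' own cluster, after the pooled simulants have been clustered. Because a
#' fresh clustering labels clusters arbitrarily, the cluster corresponding
#' to parental pool A is identified as the majority cluster of the
#' parental-A simulants.
#'
#' @param sim result of [simulate_hybrid_classes()] (for the class labels).
#' @param consensus clustering consensus (or single aligned run) of the
#'   pooled simulants, K = 2.
#' @return A `threshold_pair`: `TP1`, `TP2`, `cluster_A`, `cluster_B`.
#' @export
calibrate_thresholds <- function(sim, consensus) {
  stopifnot(inherits(consensus, "consensus_assignment"))
  if (consensus$K != 2L) stop("threshold calibration requires K = 2")
  cls <- sim$classes
  if (!any(cls == "parental_A") || !any(cls == "parental_B"))
    stop("simulated set contains no parental-class individuals")
  q <- consensus$q[match(sim$genotypes$ids, consensus$ids), , drop = FALSE]
  kA <- as.integer(names(which.max(table(
    apply(q[cls == "parental_A", , drop = FALSE], 1, which.max)))))
  kB <- 3L - kA
  structure(list(TP1 = min(q[cls == "parental_A", kA]),
                 TP2 = min(q[cls == "parental_B", kB]),
                 cluster_A = kA, cluster_B = kB),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("threshold_pair: TP1 = %.3f (cluster %d), TP2 = %.3f (cluster %d)\n",
              x$TP1, x$cluster_A, x$TP2, x$cluster_B))
  invisible(x)
}

#' Classify individuals as parents or hybrids
#'
#' Conservative rule: an individual is a parent of its majority cluster k if
#' its mean q in k reaches that cluster's threshold, otherwise a hybrid.
#' Relaxed rule: the same comparison using the lower bound of the 90%
#' credibility interval of the majority cluster's q, so the relaxed rule is
#' never stricter than the conservative one (every conservative hybrid is a
#' relaxed hybrid).
#'
#' @param consensus K = 2 consensus with credibility bounds.
#' @param thresholds a [calibrate_thresholds()] result (or list with `TP1`,
#'   `TP2`, `cluster_A`, `cluster_B`).
#' @return Data frame: individual_id, majority_cluster, q, ci_lower,
#'   threshold, conservative, relaxed (labels `parent_1`, `parent_2`,
#'   `hybrid`).
#' @export
classify_hybrids <- function(consensus, thresholds) {
  stopifnot(inherits(consensus, "consensus_assignment"))
  if (consensus$K != 2L) stop("hybrid classification requires K = 2")
  if (is.null(consensus$ci90_lower))
    stop("relaxed classification requires credibility bounds")
  tp <- numeric(2)
  tp[thresholds$cluster_A] <- thresholds$TP1
  tp[thresholds$cluster_B] <- thresholds$TP2
  k <- apply(consensus$q, 1, which.max)
  qk <- consensus$q[cbind(seq_along(k), k)]
  cik <- consensus$ci90_lower[cbind(seq_along(k), k)]
  thr <- tp[k]
  parent_lab <- paste0("parent_", k)
  data.frame(individual_id = consensus$ids, majority_cluster = as.integer(k),
             q = qk, ci_lower = cik, threshold = thr,
             conservative = ifelse(qk >= thr, parent_lab, "hybrid"),
             relaxed = ifelse(cik >= thr, parent_lab, "hybrid"),
             stringsAsFactors = FALSE)
}

#' Parental-misclassification study
#'
#' Repeatedly simulates hybrid classes from the reference pools, clusters
#' each replicate's pooled simulants afresh, applies the supplied (study)
#' thresholds, and counts parental simulants flagged as hybrids under the
#' conservative and relaxed rules.
#'
#' @param parents_a,parents_b reference parental [genotype_matrix()] pools.
#' @param thresholds the calibrated [calibrate_thresholds()] thresholds to
#'   apply to every replicate.
#' @param class_counts per-class simulant counts (default
#'   [misclassification_class_counts()]).
#' @param n_replicates number of replicates.
#' @param mcmc an [mcmc_config()] for the per-replicate clustering.
#' @param seed optional seed.
#' @return A `misclassification_result`: per-replicate data frame
#'   (`n_parental`, `flagged_conservative`, `flagged_relaxed`) and the
#'   overall rates.
#' @export
misclassification_study <- function(parents_a, parents_b, thresholds,
                                    class_counts = misclassification_class_counts(),
                                    n_replicates = 30,
                                    mcmc = desk_mcmc_config(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- hybrid_sim_config(class_counts = class_counts)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_hybrid_classes(parents_a, parents_b, cfg)
    run <- run_admixture(sim$genotypes, mcmc)
    cons <- align_runs(list(run))
    # map this replicate's arbitrary cluster labels onto the threshold pair
    cls <- sim$classes
    q <- cons$q[match(sim$genotypes$ids, cons$ids), , drop = FALSE]
    kA <- as.integer(names(which.max(table(
      apply(q[cls == "parental_A", , drop = FALSE], 1, which.max)))))
    thr_rep <- list(TP1 = thresholds$TP1, TP2 = thresholds$TP2,
                    cluster_A = kA, cluster_B = 3L - kA)
    hc <- classify_hybrids(cons, thr_rep)
    par_sel <- cls %in% c("parental_A", "parental_B")
    hp <- hc[match(sim$genotypes$ids[par_sel], hc$individual_id), ]
    reps[[r]] <- data.frame(replicate = r, n_parental = sum(par_sel),
                            flagged_conservative = sum(hp$conservative == "hybrid"),
                            flagged_relaxed = sum(hp$relaxed == "hybrid"))
  }
  tab <- do.call(rbind, reps)
  structure(list(replicates = tab,
                 rate_conservative = sum(tab$flagged_conservative) / sum(tab$n_parental),
                 rate_relaxed = sum(tab$flagged_relaxed) / sum(tab$n_parental)),
            class = "misclassification_result")
}

#' @export
print.misclassification_result <- function(x, ...) {
  cat(sprintf(paste0("misclassification_result: %d replicates; parental ",
                     "simulants flagged hybrid: %.4f (conservative), ",
                     "%.4f (relaxed)\n"),
              nrow(x$replicates), x$rate_conservative, x$rate_relaxed))
  invisible(x)
}
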