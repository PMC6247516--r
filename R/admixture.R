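#' MCMC settings for the admixture sampler
#'
#' Defaults follow the canonical settings of Bayesian admixture clustering
#' of microsatellites: a 300,000-iteration burn-in and a 1,000,000-iteration
#' chain. [desk_mcmc_config()] provides a short preset (5,000 / 20,000) that
#' resolves two sharply differentiated clusters in seconds and is the default
#' of the pipeline and the test-suite.
#'
#' @param K number of clusters (>= 1).
#' @param burn_in burn-in iterations.
#' @param length post-burn-in chain length.
#' @param thin sample-storage interval.
#' @param seed optional integer seed applied before the run.
#' @param alpha_init initial value of the symmetric Dirichlet ancestry
#'   parameter alpha.
#' @param alpha_max upper bound of the uniform prior on alpha.
#' @param alpha_prop_sd sd of the alpha random-walk Metropolis proposal.
#' @param f_init initial per-cluster drift.
#' @param f_prior_mean,f_prior_sd mean and sd of the Gamma prior on the
#'   per-cluster drift F.
#' @param f_prop_sd sd of the drift random-walk proposal.
#' @param lambda Dirichlet parameter of the ancestral-frequency prior.
#' @param pa_step sd of the ancestral-frequency pair-transfer proposal.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(K = 2, burn_in = 300000, length = 1000000, thin = 100,
                        seed = NULL, alpha_init = 1, alpha_max = 10,
                        alpha_prop_sd = 0.025, f_init = 0.05,
                        f_prior_mean = 0.01, f_prior_sd = 0.05,
                        f_prop_sd = 0.03, lambda = 1, pa_step = 0.03) {
  stopifnot(K >= 1, burn_in > 0, length > 0, thin >= 1)
  structure(list(K = as.integer(K), burn_in = as.integer(burn_in),
                 length = as.integer(length), thin = as.integer(thin),
                 seed = seed, alpha_init = alpha_init, alpha_max = alpha_max,
                 alpha_prop_sd = alpha_prop_sd, f_init = f_init,
                 f_prior_mean = f_prior_mean, f_prior_sd = f_prior_sd,
                 f_prop_sd = f_prop_sd, lambda = lambda, pa_step = pa_step),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @param ... overrides passed to [mcmc_config()].
#' @export
desk_mcmc_config <- function(K = 2, ...) {
  mcmc_config(K = K, burn_in = 5000, length = 20000, thin = 10, ...)
}

# Rao-Blackwellised posterior summaries of the ancestry fractions. Given the
# other state, q_i is Dirichlet(alpha + m_i), so the marginal posterior of
# q_ik is a mixture of Beta(alpha + m, (K-1) alpha + M_i - m) distributions
# over the visit frequencies of the origin count m; the mixture mean and its
# 5%/95% quantiles (solved by bisection on the mixture CDF) give the
# consensus q and its 90% credibility bounds with analytic tails.
rb_q_summary <- function(m_hist, n_copies, alpha, n, K, L) {
  W <- 2L * L + 1L
  if (K == 1L) {
    one <- matrix(1, n, 1)
    return(list(mean = one, lower = one, upper = one))
  }
  mh <- array(m_hist, dim = c(W, K, n))
  q_mean <- ql <- qh <- matrix(0, n, K)
  for (i in seq_len(n)) {
    M <- n_copies[i]
    for (k in seq_len(K)) {
      w <- mh[seq_len(M + 1L), k, i]
      ms <- which(w > 0) - 1L
      w <- w[ms + 1L] / sum(w)
      s1 <- alpha + ms
      s2 <- (K - 1) * alpha + M - ms
      q_mean[i, k] <- sum(w * s1) / (K * alpha + M)
      cdf <- function(x) sum(w * stats::pbeta(x, s1, s2))
      for (p in c(0.05, 0.95)) {
        lo <- 0; hi <- 1
        for (it in 1:40) {
          mid <- (lo + hi) / 2
          if (cdf(mid) < p) lo <- mid else hi <- mid
        }
        if (p == 0.05) ql[i, k] <- (lo + hi) / 2 else qh[i, k] <- (lo + hi) / 2
      }
    }
  }
  list(mean = q_mean, lower = ql, upper = qh)
}

# allele codes -> per-locus 1..A indices (missing -> 0); returns n x 2L matrix
encode_alleles <- function(gm) {
  n <- length(gm$ids); L <- length(gm$loci)
  enc <- matrix(0L, n, 2L * L)
  n_alleles <- integer(L)
  allele_levels <- vector("list", L)
  for (l in seq_len(L)) {
    a <- c(gm$alleles[, l, 1], gm$alleles[, l, 2])
    lev <- sort(unique(a[a != gm$missing_code]))
    allele_levels[[l]] <- lev
    n_alleles[l] <- max(length(lev), 1L)
    i1 <- match(gm$alleles[, l, 1], lev); i1[is.na(i1)] <- 0L
    i2 <- match(gm$alleles[, l, 2], lev); i2[is.na(i2)] <- 0L
    enc[, 2L * l - 1L] <- i1; enc[, 2L * l] <- i2
  }
  list(enc = enc, n_alleles = n_alleles, levels = allele_levels)
}

#' Run one admixture-model MCMC chain
#'
#' Gibbs sampler for the admixture model with correlated allele frequencies:
#' allele-copy origins are updated given cluster frequencies and ancestries;
#' cluster frequencies are conjugate Dirichlet updates under the F-model
#' prior (ancestral frequency vector and per-cluster drift each updated by
#' Metropolis steps); individual ancestries are Dirichlet updates; the
#' ancestry concentration alpha moves by random-walk Metropolis under a
#' uniform prior. Missing genotypes contribute no likelihood terms, so an
#' individual with no data simply retains its Dirichlet(alpha) prior.
#'
#' The model-evidence estimate is `lnPD = mean(logL) - var(logL)/2` over the
#' post-burn-in log-likelihood trace.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg an [mcmc_config()].
#' @return An `admixture_run`: `q_mean`, `q_ci90_lower`, `q_ci90_upper`
#'   (n x K), `P_mean` (per-locus K x A matrices), `alpha_trace`, `f_trace`,
#'   `loglik_trace`, `lnPD`, `K`, `ids`.
#' @export
run_admixture <- function(gm, cfg = desk_mcmc_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "mcmc_config"))
  n <- length(gm$ids)
  if (cfg$K > n) stop("K exceeds the number of individuals")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ec <- encode_alleles(gm)
  shape <- (cfg$f_prior_mean / cfg$f_prior_sd)^2
  rate <- cfg$f_prior_mean / cfg$f_prior_sd^2
  res <- .admix_gibbs(ec$enc, ec$n_alleles, cfg$K, cfg$burn_in, cfg$length,
                      cfg$thin, cfg$alpha_init, cfg$alpha_max,
                      cfg$alpha_prop_sd, cfg$f_init, shape, rate,
                      cfg$f_prop_sd, cfg$lambda, cfg$pa_step)
  qb <- rb_q_summary(res$m_hist, res$n_copies, res$alpha_mean, n, cfg$K,
                     length(gm$loci))
  q_mean <- qb$mean; ql <- qb$lower; qh <- qb$upper
  rownames(q_mean) <- rownames(ql) <- rownames(qh) <- gm$ids
  ll <- res$loglik_trace
  lnPD <- mean(ll) - stats::var(ll) / 2
  structure(list(q_mean = q_mean, q_ci90_lower = ql, q_ci90_upper = qh,
                 P_mean = res$P_mean, alpha_trace = res$alpha_trace,
                 f_trace = matrix(res$f_trace, ncol = cfg$K, byrow = TRUE),
                 loglik_trace = ll, lnPD = lnPD, K = cfg$K, ids = gm$ids,
                 allele_levels = ec$levels),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat(sprintf("admixture_run: n=%d, K=%d, lnPD=%.1f, mean alpha=%.3f\n",
              length(x$ids), x$K, x$lnPD, mean(x$alpha_trace)))
  invisible(x)
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# optimal column permutation of q onto ref (exact search, K <= 6; greedy
# matching beyond)
match_columns <- function(q, ref) {
  K <- ncol(q)
  if (K <= 6L) {
    perms <- all_permutations(K)
    costs <- apply(perms, 1, function(p) sum(abs(q[, p, drop = FALSE] - ref)))
    perms[which.min(costs), ]
  } else {
    perm <- integer(K); taken <- rep(FALSE, K)
    cost <- sapply(seq_len(K), function(j) colSums(abs(q - ref[, j])))
    for (j in order(apply(cost, 2, min))) {
      best <- order(cost[, j]); best <- best[!taken[best]][1]
      perm[j] <- best; taken[best] <- TRUE
    }
    perm
  }
}

#' Align and average multiple admixture runs
#'
#' Clustering runs label clusters arbitrarily (label switching). Runs are
#' aligned by permuting each run's columns to minimise the summed absolute
#' q-distance to a reference run (the run with the highest lnPD, so the
#' result does not depend on input order), then the aligned q matrices and
#' credibility bounds are averaged element-wise.
#'
#' @param runs list of [run_admixture()] results with equal n and K.
#' @return A `consensus_assignment`: `q`, `ci90_lower`, `ci90_upper`,
#'   `n_runs`, `permutations`, `ids`, `K`.
#' @export
align_runs <- function(runs) {
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "admixture_run")))
  K <- unique(vapply(runs, function(r) r$K, integer(1)))
  if (length(K) != 1L) stop("runs differ in K")
  ns <- unique(vapply(runs, function(r) length(r$ids), integer(1)))
  if (length(ns) != 1L) stop("runs differ in the number of individuals")
  ref_i <- which.max(vapply(runs, function(r) r$lnPD, numeric(1)))
  ref <- runs[[ref_i]]$q_mean
  perms <- lapply(runs, function(r) match_columns(r$q_mean, ref))
  qs <- Map(function(r, p) r$q_mean[, p, drop = FALSE], runs, perms)
  ql <- Map(function(r, p) r$q_ci90_lower[, p, drop = FALSE], runs, perms)
  qh <- Map(function(r, p) r$q_ci90_upper[, p, drop = FALSE], runs, perms)
  avg <- function(lst) Reduce(`+`, lst) / length(lst)
  structure(list(q = avg(qs), ci90_lower = avg(ql), ci90_upper = avg(qh),
                 n_runs = length(runs), permutations = perms,
                 ids = runs[[1]]$ids, K = K),
            class = "consensus_assignment")
}

#' @export
print.consensus_assignment <- function(x, ...) {
  cat(sprintf("consensus_assignment: n=%d, K=%d over %d run(s)\n",
              length(x$ids), x$K, x$n_runs))
  invisible(x)
}

#' Evanno delta-K table from per-K model evidence
#'
#' For each interior K, `deltaK = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`,
#' where `L(K)` is the mean lnPD over runs at K. Boundary K values have no
#' deltaK; a zero sd makes deltaK undefined (NA) rather than infinite.
#'
#' @param lnpd matrix of lnPD values, rows = runs, columns = consecutive K
#'   values (column names give K; defaults to 1..ncol).
#' @return An `evanno_table`: data frame with `K`, `mean_lnpd`, `sd_lnpd`,
#'   `deltaK`; attribute `best_K` = the interior K maximising deltaK.
#' @export
evanno_deltaK <- function(lnpd) {
  lnpd <- as.matrix(lnpd)
  if (ncol(lnpd) < 3L) stop("need at least 3 consecutive K values")
  if (nrow(lnpd) < 2L) stop("need at least 2 runs per K")
  Ks <- if (!is.null(colnames(lnpd))) as.integer(colnames(lnpd)) else seq_len(ncol(lnpd))
  if (any(diff(Ks) != 1L)) stop("K values must be consecutive")
  mu <- colMeans(lnpd); sdv <- apply(lnpd, 2, stats::sd)
  dK <- rep(NA_real_, length(Ks))
  for (j in 2:(length(Ks) - 1L)) {
    if (sdv[j] > 0) dK[j] <- abs(mu[j + 1] - 2 * mu[j] + mu[j - 1]) / sdv[j]
  }
  tab <- data.frame(K = Ks, mean_lnpd = mu, sd_lnpd = sdv, deltaK = dK,
                    row.names = NULL)
  best <- if (all(is.na(dK))) NA_integer_ else Ks[which.max(dK)]
  structure(tab, class = c("evanno_table", "data.frame"), best_K = best)
}

#' Assign individuals to their majority cluster
#'
#' @param consensus a [align_runs()] consensus (or a single run's q matrix).
#' @return Data frame with `individual_id`, `cluster` (argmax of q, ties
#'   broken by the lowest cluster index), `q_max` and a `tie` flag.
#' @export
assign_clusters <- function(consensus) {
  q <- if (inherits(consensus, "consensus_assignment")) consensus$q else consensus
  ids <- if (inherits(consensus, "consensus_assignment")) consensus$ids else rownames(q)
  cl <- apply(q, 1, which.max)
  tie <- apply(q, 1, function(r) sum(r == max(r)) > 1L)
  data.frame(individual_id = ids, cluster = as.integer(cl),
             q_max = apply(q, 1, max), tie = tie, stringsAsFactors = FALSE)
}
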