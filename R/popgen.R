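# Weir-Cockerham variance-component estimators and the permutation tests
# built on them. All permutation p-values use the includes-observed
# convention p = (b + 1) / (m + 1).

# Per-locus allele-copy and heterozygote-carrier counts by group, computed
# from the 1..A encoding of encode_alleles(). Returns, per locus, the group
# sample sizes (individuals with data), allele-copy counts and the counts of
# heterozygous individuals carrying each allele.
wc_group_stats <- function(enc, n_alleles, group_idx, n_groups) {
  L <- length(n_alleles)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    a1 <- enc[, 2L * l - 1L]; a2 <- enc[, 2L * l]
    ok <- a1 > 0L
    A <- n_alleles[l]
    g <- group_idx[ok]; x1 <- a1[ok]; x2 <- a2[ok]
    n_i <- tabulate(g, nbins = n_groups)
    pcnt <- matrix(tabulate((x1 - 1L) * n_groups + g, nbins = n_groups * A) +
                   tabulate((x2 - 1L) * n_groups + g, nbins = n_groups * A),
                   n_groups, A)
    het <- x1 != x2
    hcnt <- matrix(tabulate((x1[het] - 1L) * n_groups + g[het], nbins = n_groups * A) +
                   tabulate((x2[het] - 1L) * n_groups + g[het], nbins = n_groups * A),
                   n_groups, A)
    out[[l]] <- list(n = n_i, pcnt = pcnt, hcnt = hcnt)
  }
  out
}

# Weir-Cockerham (1984) variance components a, b, c per allele for one locus
# across r >= 2 groups (rows of pcnt/hcnt restricted to groups with data).
wc_components <- function(n_i, pcnt, hcnt) {
  r <- length(n_i)
  p_i <- pcnt / (2 * n_i)
  h_i <- hcnt / n_i
  n_bar <- mean(n_i)
  nc <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- colSums(n_i * p_i) / (r * n_bar)
  s2 <- colSums(n_i * (p_i - matrix(p_bar, r, length(p_bar), byrow = TRUE))^2) /
    ((r - 1) * n_bar)
  h_bar <- colSums(n_i * h_i) / (r * n_bar)
  a <- (n_bar / nc) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cbind(a = a, b = b, c = h_bar / 2)
}

# Single-group Weir-Cockerham f components (b, c) for one locus; the
# among-group terms vanish with r = 1.
wc_components_single <- function(n, pcnt, hcnt) {
  p <- pcnt / (2 * n); h <- hcnt / n
  b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
  cbind(b = b, c = h / 2)
}

theta_from_stats <- function(stats) {
  sa <- 0; sabc <- 0; sb <- 0; sc <- 0
  per_locus <- rep(NA_real_, length(stats))
  per_locus_abc <- matrix(0, length(stats), 3)
  for (l in seq_along(stats)) {
    st <- stats[[l]]
    keep <- st$n >= 1L
    if (sum(keep) < 2L) next
    n_i <- st$n[keep]
    if (mean(n_i) <= 1) next
    comp <- wc_components(n_i, st$pcnt[keep, , drop = FALSE],
                          st$hcnt[keep, , drop = FALSE])
    al <- sum(comp[, 1]); bl <- sum(comp[, 2]); cl <- sum(comp[, 3])
    per_locus_abc[l, ] <- c(al, bl, cl)
    if (al + bl + cl != 0) per_locus[l] <- al / (al + bl + cl)
    sa <- sa + al; sabc <- sabc + al + bl + cl; sb <- sb + bl; sc <- sc + cl
  }
  list(theta = if (sabc != 0) sa / sabc else NA_real_,
       fis = if (sb + sc != 0) 1 - sc / (sb + sc) else NA_real_,
       per_locus = per_locus, abc = per_locus_abc)
}

#' Multilocus Weir--Cockerham theta (F_ST) with bootstrap CI
#'
#' Variance components a (among groups), b (among individuals within groups)
#' and c (within individuals) are computed per allele per locus following
#' Weir & Cockerham (1984); the multilocus estimator is the ratio of summed
#' components `theta = sum(a) / sum(a + b + c)`. The 95% confidence interval
#' is a percentile bootstrap over loci.
#'
#' @param gm a [genotype_matrix()].
#' @param labels group label per individual.
#' @param n_boot bootstrap resamples over loci (0 to skip the CI).
#' @param seed optional seed for the bootstrap.
#' @return An `fst_result`: `theta`, `fis`, `per_locus_theta`, `ci95`,
#'   `n_boot`.
#' @export
wc_theta <- function(gm, labels, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), length(labels) == length(gm$ids))
  fac <- factor(labels)
  if (nlevels(fac) < 2L) stop("need at least two groups")
  ec <- encode_alleles(gm)
  stats <- wc_group_stats(ec$enc, ec$n_alleles, as.integer(fac), nlevels(fac))
  res <- theta_from_stats(stats)
  ci <- c(NA_real_, NA_real_)
  poly <- which(rowSums(res$abc != 0) > 0)
  if (n_boot > 0 && length(poly) >= 2L) {
    if (!is.null(seed)) set.seed(seed)
    abc <- res$abc
    bt <- vapply(seq_len(n_boot), function(b) {
      idx <- sample(poly, length(poly), replace = TRUE)
      s <- colSums(abc[idx, , drop = FALSE])
      s[1] / sum(s)
    }, numeric(1))
    ci <- stats::quantile(bt, c(0.025, 0.975), names = FALSE)
  }
  structure(list(theta = res$theta, fis = res$fis,
                 per_locus_theta = stats::setNames(res$per_locus, gm$loci),
                 ci95 = ci, n_boot = n_boot, groups = levels(fac)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("fst_result: theta = %.4f [%.4f-%.4f]95%% over %d loci\n",
              x$theta, x$ci95[1], x$ci95[2], length(x$per_locus_theta)))
  invisible(x)
}

#' Per-locus, per-group diversity summary
#'
#' For each locus and group: the number of distinct alleles `Na`, observed
#' heterozygosity `Ho` among amplified individuals, Nei's unbiased expected
#' heterozygosity `He = 2n/(2n-1) * (1 - sum p^2)` and the Weir--Cockerham
#' within-group `Fis`. Per-locus global theta across groups is attached.
#'
#' @param gm a [genotype_matrix()].
#' @param labels group label per individual.
#' @return A `locus_summary`: data frame `table` (locus, group, n, Na, Ho,
#'   He, Fis) plus `fst_per_locus`.
#' @export
locus_summaries <- function(gm, labels) {
  stopifnot(inherits(gm, "genotype_matrix"), length(labels) == length(gm$ids))
  fac <- factor(labels)
  ec <- encode_alleles(gm)
  stats <- wc_group_stats(ec$enc, ec$n_alleles, as.integer(fac), nlevels(fac))
  rows <- list()
  for (l in seq_along(gm$loci)) {
    st <- stats[[l]]
    for (g in seq_len(nlevels(fac))) {
      n <- st$n[g]
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus = gm$loci[l], group = levels(fac)[g], n = 0L, Na = NA_integer_,
          Ho = NA_real_, He = NA_real_, Fis = NA_real_)
        next
      }
      pc <- st$pcnt[g, ]; hc <- st$hcnt[g, ]
      Na <- sum(pc > 0)
      Ho <- sum(hc) / (2 * n)     # each het individual counted for 2 alleles
      p <- pc / (2 * n)
      He <- if (n > 0) 2 * n / (2 * n - 1) * (1 - sum(p^2)) else NA_real_
      Fis <- NA_real_
      if (Na > 1L && n > 1L) {
        comp <- wc_components_single(n, pc, hc)
        denom <- sum(comp[, 1]) + sum(comp[, 2])
        if (denom != 0) Fis <- 1 - sum(comp[, 2]) / denom
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus = gm$loci[l], group = levels(fac)[g], n = n, Na = Na,
        Ho = Ho, He = He, Fis = Fis)
    }
  }
  res <- theta_from_stats(stats)
  structure(list(table = do.call(rbind, rows),
                 fst_per_locus = stats::setNames(res$per_locus, gm$loci)),
            class = "locus_summary")
}

#' @export
print.locus_summary <- function(x, ...) {
  print(x$table, digits = 3)
  invisible(x)
}

#' Rarefied allelic richness per locus and group
#'
#' Expected number of alleles in a subsample of `g` allele copies (the
#' rarefaction used by FSTAT), `sum_u [1 - choose(N - N_u, g)/choose(N, g)]`.
#'
#' @param gm a [genotype_matrix()].
#' @param labels group labels.
#' @param g rarefaction size in allele copies; defaults to the smallest
#'   per-group, per-locus number of amplified copies.
#' @return Matrix loci x groups of rarefied richness.
#' @export
allelic_richness <- function(gm, labels, g = NULL) {
  fac <- factor(labels)
  ec <- encode_alleles(gm)
  stats <- wc_group_stats(ec$enc, ec$n_alleles, as.integer(fac), nlevels(fac))
  nmin <- min(unlist(lapply(stats, function(s) s$n[s$n > 0])))
  if (is.null(g)) g <- 2L * nmin
  out <- matrix(NA_real_, length(gm$loci), nlevels(fac),
                dimnames = list(gm$loci, levels(fac)))
  for (l in seq_along(gm$loci)) {
    st <- stats[[l]]
    for (gr in seq_len(nlevels(fac))) {
      N <- 2L * st$n[gr]
      if (N < g) next
      cnt <- st$pcnt[gr, ]
      cnt <- cnt[cnt > 0]
      out[l, gr] <- sum(1 - exp(lchoose(N - cnt, g) - lchoose(N, g)))
    }
  }
  out
}

# per-individual global allele ids (locus-offset encoding) used by the
# G-statistic permutation machinery
allele_id_lists <- function(ec) {
  offs <- c(0L, cumsum(ec$n_alleles))
  n <- nrow(ec$enc); L <- length(ec$n_alleles)
  M <- offs[L + 1L]
  ids <- vector("list", n)
  locus_of <- rep(seq_len(L), ec$n_alleles)
  for (i in seq_len(n)) {
    v <- integer(0)
    for (l in seq_len(L)) {
      a1 <- ec$enc[i, 2L * l - 1L]
      if (a1 > 0L) v <- c(v, offs[l] + a1, offs[l] + ec$enc[i, 2L * l])
    }
    ids[[i]] <- v
  }
  list(ids = ids, M = M, locus_of = locus_of)
}

g_stat_counts <- function(c1, c2, locus_of) {
  tot <- c1 + c2
  use <- tot > 0
  r1 <- rowsum(c1[use], locus_of[use]); r2 <- rowsum(c2[use], locus_of[use])
  cl <- rowsum(tot[use], locus_of[use])
  lf <- factor(locus_of[use])
  e1 <- (r1[lf] / cl[lf]) * tot[use]
  e2 <- (r2[lf] / cl[lf]) * tot[use]
  o1 <- c1[use]; o2 <- c2[use]
  2 * (sum(o1[o1 > 0] * log(o1[o1 > 0] / e1[o1 > 0])) +
       sum(o2[o2 > 0] * log(o2[o2 > 0] / e2[o2 > 0])))
}

#' Pairwise theta and exact G-tests of differentiation
#'
#' For each pair of groups, the Weir--Cockerham theta and a log-likelihood
#' G statistic on allele counts (summed over loci), with significance from
#' permuting multilocus genotypes between the two groups.
#'
#' @param gm a [genotype_matrix()].
#' @param labels group labels.
#' @param n_perm permutations per pair.
#' @param seed optional seed.
#' @return A `pairwise_fst` list: `theta` and `p_value` matrices, `n_perm`.
#' @export
pairwise_fst <- function(gm, labels, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  fac <- factor(labels)
  sizes <- table(fac)
  keep <- names(sizes)[sizes >= 2]
  if (length(keep) < length(sizes))
    warning("groups with fewer than 2 individuals excluded: ",
            paste(setdiff(names(sizes), keep), collapse = ", "))
  if (length(keep) < 2L) stop("need at least two groups of size >= 2")
  ec <- encode_alleles(gm)
  al <- allele_id_lists(ec)
  th <- matrix(NA_real_, length(keep), length(keep), dimnames = list(keep, keep))
  pv <- th
  for (i in seq_along(keep)[-length(keep)]) {
    for (j in (i + 1L):length(keep)) {
      ii <- which(fac == keep[i]); jj <- which(fac == keep[j])
      sub <- c(ii, jj)
      lab <- rep(c(1L, 2L), c(length(ii), length(jj)))
      th[i, j] <- th[j, i] <-
        wc_theta(subset_genotypes(gm, sub), lab, n_boot = 0)$theta
      cnt <- function(idx) tabulate(unlist(al$ids[idx]), nbins = al$M)
      g_obs <- g_stat_counts(cnt(ii), cnt(jj), al$locus_of)
      b <- 0L
      for (p in seq_len(n_perm)) {
        pi <- sample(sub, length(ii))
        gp <- g_stat_counts(cnt(pi), cnt(setdiff(sub, pi)), al$locus_of)
        if (gp >= g_obs - 1e-12) b <- b + 1L
      }
      pv[i, j] <- pv[j, i] <- (b + 1) / (n_perm + 1)
    }
  }
  structure(list(theta = th, p_value = pv, n_perm = n_perm),
            class = "pairwise_fst")
}

#' Hardy--Weinberg equilibrium permutation test
#'
#' Per locus and group, the Weir--Cockerham within-group f is compared to its
#' permutation null obtained by re-pairing the group's pooled allele copies
#' at random (FSTAT-style randomization). Since allele counts are fixed
#' under the null, f is a monotone function of the heterozygote count, which
#' is the quantity permuted.
#'
#' @param gm a [genotype_matrix()].
#' @param labels group labels.
#' @param n_perm permutations.
#' @param alternative `"two.sided"` or `"deficit"` (heterozygote deficit,
#'   the signature of null alleles and inbreeding).
#' @param seed optional seed.
#' @return Data frame: locus, group, n, f, p, p_bonferroni, significant.
#' @export
hwe_test <- function(gm, labels, n_perm = 10000,
                     alternative = c("two.sided", "deficit"), seed = NULL) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  fac <- factor(labels)
  ec <- encode_alleles(gm)
  rows <- list()
  for (l in seq_along(gm$loci)) {
    a1 <- ec$enc[, 2L * l - 1L]; a2 <- ec$enc[, 2L * l]
    for (g in levels(fac)) {
      sel <- fac == g & a1 > 0L
      n <- sum(sel)
      f <- p <- NA_real_
      if (n >= 5L) {
        x1 <- a1[sel]; x2 <- a2[sel]
        nall <- length(unique(c(x1, x2)))
        if (nall > 1L) {
          het_obs <- sum(x1 != x2)
          pc <- tabulate(c(x1, x2))
          hc <- tabulate(c(x1[x1 != x2], x2[x1 != x2]), nbins = length(pc))
          comp <- wc_components_single(n, pc, hc)
          f <- 1 - sum(comp[, 2]) / (sum(comp[, 1]) + sum(comp[, 2]))
          hp <- .hwe_perm_het(as.integer(c(rbind(x1, x2))), as.integer(n_perm))
          p_lo <- (sum(hp <= het_obs) + 1) / (n_perm + 1)  # deficit
          p_hi <- (sum(hp >= het_obs) + 1) / (n_perm + 1)  # excess
          p <- if (alternative == "deficit") p_lo else min(1, 2 * min(p_lo, p_hi))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus = gm$loci[l], group = g, n = n, f = f, p = p)
    }
  }
  out <- do.call(rbind, rows)
  n_tests <- sum(!is.na(out$p))
  out$p_bonferroni <- pmin(1, out$p * n_tests)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < 0.05
  out
}

#' Linkage-disequilibrium permutation test per locus pair
#'
#' Genotypic association: for each group and locus pair, a log-likelihood G
#' statistic on the two-locus genotype contingency table, with the null
#' built by permuting one locus's genotypes among individuals within the
#' group. Tables with fewer than two genotype classes at either locus are
#' reported NA.
#'
#' @param gm a [genotype_matrix()].
#' @param labels group labels.
#' @param n_perm permutations.
#' @param seed optional seed.
#' @return Data frame: locus1, locus2, group, G, p, p_bonferroni,
#'   significant.
#' @export
ld_test <- function(gm, labels, n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fac <- factor(labels)
  L <- length(gm$loci)
  if (L < 2L) stop("need at least two loci")
  geno_id <- function(l) {
    a1 <- gm$alleles[, l, 1]; a2 <- gm$alleles[, l, 2]
    id <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    id[a1 == gm$missing_code] <- NA
    id
  }
  gtab <- vapply(seq_len(L), geno_id, character(length(gm$ids)))
  g_of_table <- function(tt) {
    e <- outer(rowSums(tt), colSums(tt)) / sum(tt)
    2 * sum(tt[tt > 0] * log(tt[tt > 0] / e[tt > 0]))
  }
  rows <- list()
  for (l1 in seq_len(L - 1L)) {
    for (l2 in (l1 + 1L):L) {
      for (g in levels(fac)) {
        sel <- fac == g & !is.na(gtab[, l1]) & !is.na(gtab[, l2])
        Gv <- p <- NA_real_
        x <- gtab[sel, l1]; y <- gtab[sel, l2]
        if (sum(sel) >= 5L && length(unique(x)) > 1L && length(unique(y)) > 1L) {
          tt <- table(x, y)
          Gv <- g_of_table(tt)
          b <- 0L
          for (pp in seq_len(n_perm)) {
            if (g_of_table(table(x, sample(y))) >= Gv - 1e-12) b <- b + 1L
          }
          p <- (b + 1) / (n_perm + 1)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          locus1 = gm$loci[l1], locus2 = gm$loci[l2], group = g, G = Gv, p = p)
      }
    }
  }
  out <- do.call(rbind, rows)
  n_tests <- sum(!is.na(out$p))
  out$p_bonferroni <- pmin(1, out$p * n_tests)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < 0.05
  out
}

#' Null-allele scan with exact binomial significance
#'
#' The per-locus, per-group null-allele frequency is estimated from the
#' heterozygote deficit: Chakraborty's `r = (He - Ho) / (He + Ho)` (default)
#' or Brookfield's first estimator `(He - Ho) / (1 + He)`. Significance of a
#' homozygote excess is an exact binomial test of the observed homozygote
#' count against its Hardy--Weinberg expectation (one-sided).
#'
#' @param gm a [genotype_matrix()].
#' @param labels group labels.
#' @param estimator `"chakraborty"` or `"brookfield1"`.
#' @return Data frame: locus, group, n, Ho, He, null_freq, p.
#' @export
null_allele_scan <- function(gm, labels,
                             estimator = c("chakraborty", "brookfield1")) {
  estimator <- match.arg(estimator)
  fac <- factor(labels)
  ec <- encode_alleles(gm)
  rows <- list()
  for (l in seq_along(gm$loci)) {
    a1 <- ec$enc[, 2L * l - 1L]; a2 <- ec$enc[, 2L * l]
    for (g in levels(fac)) {
      sel <- fac == g & a1 > 0L
      n <- sum(sel)
      Ho <- He <- r <- p <- NA_real_
      if (n >= 10L) {
        x1 <- a1[sel]; x2 <- a2[sel]
        Ho <- mean(x1 != x2)
        pfreq <- tabulate(c(x1, x2)) / (2 * n)
        He <- 2 * n / (2 * n - 1) * (1 - sum(pfreq^2))
        if (He > 0) {
          r <- if (estimator == "chakraborty") (He - Ho) / (He + Ho)
               else (He - Ho) / (1 + He)
          hom_exp <- sum(pfreq^2)
          p <- stats::binom.test(sum(x1 == x2), n, hom_exp,
                                 alternative = "greater")$p.value
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus = gm$loci[l], group = g, n = n, Ho = Ho, He = He,
        null_freq = r, p = p)
    }
  }
  do.call(rbind, rows)
}

#' Sex-biased dispersal test on F_ST
#'
#' The statistic is `theta_F - theta_M`, each sex's multilocus theta computed
#' over sites; members of the dispersing sex are expected to be less
#' structured (lower theta). The null distribution permutes sex labels
#' within sites; the test is one-sided for the hypothesised dispersing sex.
#'
#' @param gm a [genotype_matrix()].
#' @param sex per-individual `"F"`/`"M"` (others dropped).
#' @param site per-individual site labels.
#' @param dispersing_sex `"male"` or `"female"`.
#' @param n_rand randomizations.
#' @param seed optional seed.
#' @return A `perm_test` list: `statistic` (theta_F - theta_M), `theta_f`,
#'   `theta_m`, `p_value`, `n_permutations`, `tail`.
#' @export
sex_biased_dispersal_test <- function(gm, sex, site,
                                      dispersing_sex = c("male", "female"),
                                      n_rand = 1000, seed = NULL) {
  dispersing_sex <- match.arg(dispersing_sex)
  if (!is.null(seed)) set.seed(seed)
  keep <- sex %in% c("F", "M")
  gm2 <- subset_genotypes(gm, which(keep))
  sex <- sex[keep]; site <- as.character(site)[keep]
  ok_sites <- names(which(tapply(sex == "F", site, any) &
                          tapply(sex == "M", site, any)))
  if (length(ok_sites) < length(unique(site)))
    warning("sites lacking one sex excluded: ",
            paste(setdiff(unique(site), ok_sites), collapse = ", "))
  if (length(ok_sites) < 2L) stop("need both sexes present in at least two sites")
  sel <- site %in% ok_sites
  gm2 <- subset_genotypes(gm2, which(sel)); sex <- sex[sel]; site <- site[sel]
  ec <- encode_alleles(gm2)
  site_f <- factor(site)
  theta_by_sex <- function(sx) {
    fac <- droplevels(site_f[sx])
    st <- wc_group_stats(ec$enc[sx, , drop = FALSE], ec$n_alleles,
                         as.integer(fac), nlevels(fac))
    theta_from_stats(st)$theta
  }
  stat <- function(sexv) theta_by_sex(sexv == "F") - theta_by_sex(sexv == "M")
  obs <- stat(sex)
  perm_stats <- vapply(seq_len(n_rand), function(i) {
    sp <- sex
    for (s in ok_sites) {
      idx <- which(site == s)
      sp[idx] <- sample(sp[idx])
    }
    stat(sp)
  }, numeric(1))
  b <- if (dispersing_sex == "male") sum(perm_stats >= obs - 1e-12)
       else sum(perm_stats <= obs + 1e-12)
  structure(list(statistic = obs,
                 theta_f = theta_by_sex(sex == "F"),
                 theta_m = theta_by_sex(sex == "M"),
                 p_value = (b + 1) / (n_rand + 1),
                 n_permutations = n_rand,
                 tail = paste0("one-sided (dispersing: ", dispersing_sex, ")")),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("perm_test: statistic = %.4f, p = %.4f (%s, %d permutations)\n",
              x$statistic, x$p_value, x$tail, x$n_permutations))
  invisible(x)
}
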