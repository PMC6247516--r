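# End-to-end orchestration: data (simulated or read from disk) -> locus
# quality screens -> admixture clustering with Evanno model selection ->
# hybrid detection -> population-genetic statistics -> mitochondrial
# haplogrouping and discordance -> phenotype comparisons.

#' Pipeline configuration
#'
#' Either `simulate = TRUE` with a [sim_config()], or input paths to a
#' genotype file, a metadata CSV and an aligned FASTA. One global seed
#' deterministically derives per-stage seeds, so stages can be re-run in
#' isolation and the full report is reproducible.
#'
#' @param simulate generate the dataset with [simulate_dataset()]?
#' @param sim a [sim_config()] (simulate mode).
#' @param genotype_path,genotype_dialect,metadata_path,fasta_path input
#'   files (read mode).
#' @param mcmc an [mcmc_config()] template; its K is set per stage.
#' @param n_runs clustering runs per K for the consensus and the Evanno
#'   scan.
#' @param k_range K values scanned for the Evanno table.
#' @param hybrid a [hybrid_sim_config()] for threshold calibration.
#' @param run_misclassification run the replicated parental-
#'   misclassification study?
#' @param n_perm permutations for the HWE/LD/differentiation tests.
#' @param haplogroup_cutoff raw-distance cutoff for the haplogroup
#'   partition.
#' @param seed global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, sim = sim_config(),
                            genotype_path = NULL,
                            genotype_dialect = "csv_wide",
                            metadata_path = NULL, fasta_path = NULL,
                            mcmc = desk_mcmc_config(),
                            n_runs = 3, k_range = 1:4,
                            hybrid = hybrid_sim_config(),
                            run_misclassification = TRUE,
                            n_perm = 1000,
                            haplogroup_cutoff = 0.02,
                            seed = 1) {
  if (!simulate && is.null(genotype_path))
    stop("either simulate = TRUE or a genotype_path is required")
  structure(list(simulate = simulate, sim = sim,
                 genotype_path = genotype_path,
                 genotype_dialect = genotype_dialect,
                 metadata_path = metadata_path, fasta_path = fasta_path,
                 mcmc = mcmc, n_runs = n_runs, k_range = k_range,
                 hybrid = hybrid,
                 run_misclassification = run_misclassification,
                 n_perm = n_perm, haplogroup_cutoff = haplogroup_cutoff,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# deterministic per-stage seed derivation, kept within 32-bit integer range
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

#' Drop quality-flagged loci
#'
#' Removes loci with a significant null-allele signal (exact binomial p <
#' 0.05) or a Bonferroni-significant Hardy--Weinberg departure in either
#' group.
#'
#' @param null_scan result of [null_allele_scan()].
#' @param hwe result of [hwe_test()].
#' @param loci full locus list.
#' @param min_retained abort below this many retained loci.
#' @return Character vector of retained loci; flagged loci attached as
#'   attribute `"excluded"`.
#' @export
exclude_loci <- function(null_scan, hwe, loci, min_retained = 5) {
  bad_null <- unique(null_scan$locus[!is.na(null_scan$p) & null_scan$p < 0.05])
  bad_hwe <- unique(hwe$locus[hwe$significant])
  flagged <- union(bad_null, bad_hwe)
  retained <- setdiff(loci, flagged)
  if (length(retained) < min_retained)
    stop(sprintf("only %d loci would be retained (minimum %d)",
                 length(retained), min_retained))
  attr(retained, "excluded") <- flagged
  retained
}

cluster_consensus <- function(gm, mcmc, K, n_runs, seed) {
  runs <- lapply(seq_len(n_runs), function(r) {
    cfg <- mcmc; cfg$K <- as.integer(K); cfg$seed <- seed + r
    run_admixture(gm, cfg)
  })
  list(runs = runs, consensus = align_runs(runs))
}

#' Run the full analysis pipeline
#'
#' Stage order: dataset (simulated or read), validation, locus quality
#' screens on a provisional K = 2 clustering, locus exclusion and
#' re-clustering on the retained loci, Evanno scan over `k_range`,
#' consensus at the selected K, hybrid-threshold calibration and
#' classification, Weir--Cockerham statistics, sex-biased dispersal tests
#' per cluster, mitochondrial haplogrouping and cyto-nuclear discordance,
#' and nested ANOVA of the phenotypes after excluding relaxed-rule nuclear
#' hybrids and mtDNA-discordant individuals.
#'
#' @param cfg a [pipeline_config()].
#' @return A `cryptohyb_report` list; see the fields in the examples of the
#'   package vignette.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  report <- list(seed = cfg$seed)

  # ---- stage: data ------------------------------------------------------
  if (cfg$simulate) {
    ds <- simulate_dataset(cfg$sim, seed = stage_seed(cfg$seed, "data"))
    gm <- ds$genotypes; metadata <- ds$metadata
    sequences <- ds$sequences; truth <- ds$truth
  } else {
    gm <- read_genotypes(cfg$genotype_path, cfg$genotype_dialect)
    metadata <- if (!is.null(cfg$metadata_path))
      utils::read.csv(cfg$metadata_path, stringsAsFactors = FALSE) else NULL
    sequences <- if (!is.null(cfg$fasta_path)) read_fasta(cfg$fasta_path) else NULL
    truth <- NULL
  }
  report$validation <- validate_dataset(gm, metadata)

  # ---- stage: provisional clusters for the locus screens ----------------
  message("clustering (provisional, all loci) ...")
  prov <- cluster_consensus(gm, cfg$mcmc, K = 2, n_runs = 1,
                            seed = stage_seed(cfg$seed, "provisional"))
  prov_labels <- assign_clusters(prov$consensus)$cluster

  # ---- stage: locus quality screens -------------------------------------
  message("locus quality screens ...")
  set.seed(stage_seed(cfg$seed, "screens"))
  null_scan <- null_allele_scan(gm, prov_labels)
  hwe <- hwe_test(gm, prov_labels, n_perm = cfg$n_perm)
  retained <- exclude_loci(null_scan, hwe, gm$loci)
  report$locus_screens <- list(null_alleles = null_scan, hwe = hwe,
                               retained = retained,
                               excluded = attr(retained, "excluded"))
  gm_r <- if (length(retained) < length(gm$loci))
    subset_genotypes(gm, loci = retained) else gm

  # ---- stage: Evanno K scan ---------------------------------------------
  message("Evanno scan over K = ", paste(range(cfg$k_range), collapse = "-"), " ...")
  lnpd <- matrix(NA_real_, cfg$n_runs, length(cfg$k_range),
                 dimnames = list(NULL, cfg$k_range))
  cons_by_k <- list()
  for (j in seq_along(cfg$k_range)) {
    cc <- cluster_consensus(gm_r, cfg$mcmc, K = cfg$k_range[j], cfg$n_runs,
                            seed = stage_seed(cfg$seed, paste0("evanno_k", cfg$k_range[j])))
    lnpd[, j] <- vapply(cc$runs, function(r) r$lnPD, numeric(1))
    cons_by_k[[j]] <- cc$consensus
  }
  report$evanno <- evanno_deltaK(lnpd)
  best_K <- attr(report$evanno, "best_K")
  report$best_K <- best_K

  # ---- stage: consensus at the selected K -------------------------------
  consensus <- cons_by_k[[match(best_K, cfg$k_range)]]
  report$consensus <- consensus
  asg <- assign_clusters(consensus)
  report$cluster_sizes <- table(asg$cluster)

  # ---- stage: hybrids (K = 2 only) --------------------------------------
  if (best_K == 2L) {
    message("hybrid simulation and threshold calibration ...")
    parents <- select_reference_parents(consensus, cfg$hybrid$n_reference_parents)
    pa <- subset_genotypes(gm_r, parents$cluster1)
    pb <- subset_genotypes(gm_r, parents$cluster2)
    set.seed(stage_seed(cfg$seed, "hybrid_sim"))
    sim <- simulate_hybrid_classes(pa, pb, cfg$hybrid)
    mc <- cfg$mcmc; mc$K <- 2L; mc$seed <- stage_seed(cfg$seed, "hybrid_mcmc")
    sim_cons <- align_runs(list(run_admixture(sim$genotypes, mc)))
    thresholds <- calibrate_thresholds(sim, sim_cons)
    report$thresholds <- thresholds
    report$hybrids <- classify_hybrids(consensus, thresholds)
    report$n_hybrids <- c(
      conservative = sum(report$hybrids$conservative == "hybrid"),
      relaxed = sum(report$hybrids$relaxed == "hybrid"))
    if (cfg$run_misclassification) {
      message("misclassification study (", cfg$hybrid$n_replicates, " replicates) ...")
      report$misclassification <- misclassification_study(
        pa, pb, thresholds, n_replicates = cfg$hybrid$n_replicates,
        mcmc = mc, seed = stage_seed(cfg$seed, "misclassification"))
    }
  }

  # ---- stage: population genetics ---------------------------------------
  message("population-genetic statistics ...")
  labels <- asg$cluster
  report$locus_summary <- locus_summaries(gm_r, labels)
  report$theta <- wc_theta(gm_r, labels, n_boot = 1000,
                           seed = stage_seed(cfg$seed, "boot"))
  report$allelic_richness <- allelic_richness(gm_r, labels)
  if (!is.null(metadata)) {
    md <- metadata[match(gm_r$ids, metadata$individual_id), ]
    if (!is.null(md$site) && length(unique(md$site)) >= 2) {
      # spatial structure among caves, within each cluster
      pw <- list()
      for (k in sort(unique(labels))) {
        sel <- labels == k
        pw[[as.character(k)]] <- tryCatch(
          pairwise_fst(subset_genotypes(gm_r, which(sel)), md$site[sel],
                       n_perm = cfg$n_perm,
                       seed = stage_seed(cfg$seed, paste0("caves", k))),
          error = function(e) e$message)
      }
      report$cave_fst <- pw
      disp <- list()
      for (k in sort(unique(labels))) {
        sel <- labels == k
        gmk <- subset_genotypes(gm_r, which(sel))
        disp[[as.character(k)]] <- tryCatch(list(
          male = sex_biased_dispersal_test(gmk, md$sex[sel], md$site[sel],
                                           "male", n_rand = cfg$n_perm,
                                           seed = stage_seed(cfg$seed, paste0("disp_m", k))),
          female = sex_biased_dispersal_test(gmk, md$sex[sel], md$site[sel],
                                             "female", n_rand = cfg$n_perm,
                                             seed = stage_seed(cfg$seed, paste0("disp_f", k)))),
          error = function(e) e$message)
      }
      report$sex_dispersal <- disp
    }
  }

  # ---- stage: mitochondrial analyses ------------------------------------
  if (!is.null(sequences)) {
    message("mitochondrial haplogrouping ...")
    dm <- raw_distance(sequences)
    part <- haplogroup_partition(dm, cfg$haplogroup_cutoff)
    nuclear <- stats::setNames(paste0("c", asg$cluster), asg$individual_id)
    # name mt haplogroups after the majority nuclear cluster of their members
    shared <- intersect(names(nuclear), names(part$groups))
    map <- tapply(nuclear[shared], part$groups[shared],
                  function(x) names(which.max(table(x))))
    mt <- stats::setNames(unname(map[as.character(part$groups)]),
                          names(part$groups))
    report$haplogroups <- part
    report$discordance <- cytonuclear_discordance(nuclear, mt)
  }

  # ---- stage: phenotypes -------------------------------------------------
  if (!is.null(metadata) && !is.null(metadata$forearm_mm)) {
    message("phenotype comparisons ...")
    excl <- character(0)
    if (!is.null(report$hybrids))
      excl <- report$hybrids$individual_id[report$hybrids$relaxed == "hybrid"]
    if (!is.null(report$discordance) && !is.null(sequences)) {
      shared <- intersect(names(nuclear), names(mt))
      excl <- union(excl, shared[nuclear[shared] != mt[shared]])
    }
    md <- metadata[match(gm_r$ids, metadata$individual_id), ]
    keep <- !(gm_r$ids %in% excl)
    grp <- paste0("c", asg$cluster)
    report$phenotypes <- list(excluded = excl)
    report$phenotypes$forearm <- tryCatch(
      nested_anova(md$forearm_mm[keep], md$sex[keep], grp[keep]),
      error = function(e) e$message)
    if (!is.null(md$fme_khz)) {
      fme <- stats::setNames(md$fme_khz, gm_r$ids)
      out <- screen_outliers(fme[keep], grp[keep])
      report$phenotypes$fme_outliers <- out
      keep_f <- keep & !(gm_r$ids %in% out)
      report$phenotypes$fme <- tryCatch(
        nested_anova(md$fme_khz[keep_f], md$sex[keep_f], grp[keep_f]),
        error = function(e) e$message)
    }
  }

  if (!is.null(truth)) report$truth <- truth
  class(report) <- "cryptohyb_report"
  report
}

#' @export
print.cryptohyb_report <- function(x, ...) {
  cat("cryptohyb_report\n")
  cat(sprintf("  individuals: %d, loci: %d (retained %d), amplification %.1f%%\n",
              x$validation$n_individuals, x$validation$n_loci,
              length(x$locus_screens$retained),
              100 * x$validation$amplification_rate))
  cat(sprintf("  selected K = %d; cluster sizes: %s\n", x$best_K,
              paste(x$cluster_sizes, collapse = "/")))
  if (!is.null(x$theta))
    cat(sprintf("  theta = %.3f [%.3f-%.3f]\n", x$theta$theta,
                x$theta$ci95[1], x$theta$ci95[2]))
  if (!is.null(x$thresholds))
    cat(sprintf("  thresholds TP1 = %.3f, TP2 = %.3f; hybrids: %d conservative, %d relaxed\n",
                x$thresholds$TP1, x$thresholds$TP2,
                x$n_hybrids["conservative"], x$n_hybrids["relaxed"]))
  if (!is.null(x$misclassification))
    cat(sprintf("  parental misclassification rate: %.4f conservative, %.4f relaxed\n",
                x$misclassification$rate_conservative,
                x$misclassification$rate_relaxed))
  if (!is.null(x$discordance))
    cat(sprintf("  cyto-nuclear discordance: %s\n",
                paste(sprintf("%s=%.3f", names(x$discordance$proportions),
                              x$discordance$proportions), collapse = ", ")))
  invisible(x)
}

#' Write a report's main tables to a directory
#'
#' Writes the consensus q-matrix, hybrid classification and locus summary as
#' TSV and the scalar summary as JSON. Numbers do not depend on the output
#' directory.
#'
#' @param report a [run_pipeline()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cryptohyb_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q <- data.frame(individual_id = report$consensus$ids, report$consensus$q,
                  report$consensus$ci90_lower, report$consensus$ci90_upper)
  names(q) <- c("individual_id", paste0("q_", seq_len(report$best_K)),
                paste0("ci_low_", seq_len(report$best_K)),
                paste0("ci_high_", seq_len(report$best_K)))
  utils::write.table(q, file.path(dir, "consensus_q.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(report$hybrids))
    utils::write.table(report$hybrids, file.path(dir, "hybrids.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$locus_summary$table,
                     file.path(dir, "locus_summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summ <- list(seed = report$seed, best_K = report$best_K,
               cluster_sizes = as.integer(report$cluster_sizes),
               theta = report$theta$theta, theta_ci = report$theta$ci95,
               amplification_rate = report$validation$amplification_rate)
  if (!is.null(report$thresholds))
    summ$thresholds <- c(TP1 = report$thresholds$TP1, TP2 = report$thresholds$TP2)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
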