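#' Construct a diploid genotype matrix
#'
#' The substrate of all nuclear analyses: an `n x L x 2` array of integer
#' allele codes (microsatellite allele sizes or arbitrary positive integers)
#' for `n` individuals typed at `L` co-dominant loci. Missing genotypes are
#' coded by a sentinel (default `-9`, the convention of STRUCTURE-style input
#' files); both allele copies of a locus must be missing or present together
#' -- a half-missing call is an invalid record, not haploid data.
#'
#' @param alleles integer array of dimension `c(n, L, 2)`, or an `n x 2L`
#'   matrix with the two columns of each locus adjacent.
#' @param ids character vector of unique individual identifiers.
#' @param loci character vector of unique locus names.
#' @param missing_code integer sentinel for missing calls.
#' @return An object of class `genotype_matrix` with fields `ids`, `loci`,
#'   `alleles` (the `n x L x 2` array) and `missing_code`.
#' @export
genotype_matrix <- function(alleles, ids = NULL, loci = NULL, missing_code = -9L) {
  if (is.matrix(alleles)) {
    if (ncol(alleles) %% 2L != 0L)
      stop("genotype matrix must have an even number of allele columns")
    L <- ncol(alleles) %/% 2L
    alleles <- array(c(alleles[, seq(1L, 2L * L, by = 2L), drop = FALSE],
                       alleles[, seq(2L, 2L * L, by = 2L), drop = FALSE]),
                     dim = c(nrow(alleles), L, 2L))
  }
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L)
    stop("'alleles' must be an n x L x 2 array or an n x 2L matrix")
  n <- dim(alleles)[1]; L <- dim(alleles)[2]
  if (n < 1L || L < 1L) stop("need at least one individual and one locus")
  if (is.null(ids)) ids <- sprintf("ind_%03d", seq_len(n))
  if (is.null(loci)) loci <- sprintf("locus_%02d", seq_len(L))
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  if (anyDuplicated(loci)) stop("duplicate locus names")
  if (length(ids) != n || length(loci) != L)
    stop("id/locus name lengths do not match allele array")
  storage.mode(alleles) <- "integer"
  alleles[is.na(alleles)] <- as.integer(missing_code)
  miss1 <- alleles[, , 1, drop = FALSE] == missing_code
  miss2 <- alleles[, , 2, drop = FALSE] == missing_code
  half <- which(miss1 != miss2, arr.ind = TRUE)
  if (nrow(half) > 0L)
    stop(sprintf("half-missing genotype for individual '%s' at locus '%s'",
                 ids[half[1, 1]], loci[half[1, 2]]))
  bad <- !miss1 & (alleles[, , 1, drop = FALSE] <= 0L)
  bad2 <- !miss2 & (alleles[, , 2, drop = FALSE] <= 0L)
  if (any(bad) || any(bad2)) stop("non-missing allele codes must be positive integers")
  structure(list(ids = as.character(ids), loci = as.character(loci),
                 alleles = alleles, missing_code = as.integer(missing_code)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nm <- sum(x$alleles[, , 1] == x$missing_code)
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing calls)\n",
              length(x$ids), length(x$loci),
              100 * nm / (length(x$ids) * length(x$loci))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$ids), length(x$loci))

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param gm a `genotype_matrix`.
#' @param individuals indices or ids of individuals to keep (default all).
#' @param loci indices or names of loci to keep (default all).
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(gm, individuals = NULL, loci = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ii <- if (is.null(individuals)) seq_along(gm$ids) else {
    if (is.character(individuals)) match(individuals, gm$ids) else individuals
  }
  ll <- if (is.null(loci)) seq_along(gm$loci) else {
    if (is.character(loci)) match(loci, gm$loci) else loci
  }
  if (anyNA(ii)) stop("unknown individual id in subset")
  if (anyNA(ll)) stop("unknown locus name in subset")
  genotype_matrix(gm$alleles[ii, ll, , drop = FALSE], ids = gm$ids[ii],
                  loci = gm$loci[ll], missing_code = gm$missing_code)
}

#' Read a genotype matrix from disk
#'
#' Two dialects are supported. `csv_wide`: a header row `id,<locus>_a,
#' <locus>_b,...` followed by one row per individual. `structure_2row`: a
#' whitespace-separated file with one optional locus-name header line and two
#' consecutive rows per individual (one per haploid allele set), the first
#' field of each row being the individual id. Missing alleles may be coded as
#' any non-positive integer or `NA`; they are normalised to the `-9` sentinel.
#'
#' @param path path to the file.
#' @param dialect `"csv_wide"` or `"structure_2row"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("csv_wide", "structure_2row")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv_wide") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("csv_wide needs an id column plus allele columns")
    ids <- as.character(df[[1]])
    ac <- ncol(df) - 1L
    if (ac %% 2L != 0L) stop("odd number of allele columns in csv_wide file")
    loci <- sub("_a$", "", names(df)[seq(2L, ncol(df), by = 2L)])
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "integer"
    mat[is.na(mat) | mat <= 0L] <- -9L
    genotype_matrix(mat, ids = ids, loci = loci)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    tok <- strsplit(trimws(lines), "[ \t]+")
    nt <- lengths(tok)
    loci <- NULL
    if (length(unique(nt)) > 1L && nt[1] == nt[2] - 1L) {
      loci <- tok[[1]]; tok <- tok[-1]; nt <- nt[-1]
    }
    if (length(unique(nt)) != 1L) stop("ragged rows in structure_2row file")
    if (length(tok) %% 2L != 0L) stop("structure_2row needs two rows per individual")
    L <- nt[1] - 1L
    if (L < 1L) stop("no locus columns in structure_2row file")
    ids1 <- vapply(tok[seq(1L, length(tok), by = 2L)], `[`, "", 1L)
    ids2 <- vapply(tok[seq(2L, length(tok), by = 2L)], `[`, "", 1L)
    if (!identical(ids1, ids2)) stop("row pairs of structure_2row file disagree on ids")
    n <- length(ids1)
    a1 <- matrix(as.integer(unlist(lapply(tok[seq(1L, length(tok), by = 2L)], `[`, -1L))),
                 nrow = n, byrow = TRUE)
    a2 <- matrix(as.integer(unlist(lapply(tok[seq(2L, length(tok), by = 2L)], `[`, -1L))),
                 nrow = n, byrow = TRUE)
    a1[is.na(a1) | a1 <= 0L] <- -9L
    a2[is.na(a2) | a2 <= 0L] <- -9L
    genotype_matrix(array(c(a1, a2), dim = c(n, L, 2L)), ids = ids1, loci = loci)
  }
}

#' Write a genotype matrix to disk
#'
#' Inverse of [read_genotypes()]: `read_genotypes(write_genotypes(gm))`
#' returns an identical matrix for both dialects (the structure dialect
#' writes a locus-name header line so names round-trip).
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param dialect `"csv_wide"` or `"structure_2row"`.
#' @export
write_genotypes <- function(gm, path, dialect = c("csv_wide", "structure_2row")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  dialect <- match.arg(dialect)
  n <- length(gm$ids); L <- length(gm$loci)
  if (dialect == "csv_wide") {
    wide <- matrix(0L, n, 2L * L)
    wide[, seq(1L, 2L * L, by = 2L)] <- gm$alleles[, , 1]
    wide[, seq(2L, 2L * L, by = 2L)] <- gm$alleles[, , 2]
    colnames(wide) <- as.vector(rbind(paste0(gm$loci, "_a"), paste0(gm$loci, "_b")))
    df <- data.frame(id = gm$ids, wide, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(gm$loci, collapse = " "), con)
    for (i in seq_len(n)) {
      writeLines(paste(c(gm$ids[i], gm$alleles[i, , 1]), collapse = " "), con)
      writeLines(paste(c(gm$ids[i], gm$alleles[i, , 2]), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' All records must have the same length (the sequences are expected to be a
#' pre-aligned mitochondrial barcode fragment). Lowercase bases are
#' normalised to uppercase; any character outside `A,C,G,T,-` is treated as
#' `N` downstream.
#'
#' @param path FASTA file path.
#' @return An object of class `aligned_seqs`: list with `ids`, `seqs`
#'   (character vector of equal-length uppercase strings) and `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no sequences in ", path)
  ids <- names(dna)
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  chars <- lapply(as.character(dna), function(x) toupper(paste(x, collapse = "")))
  lens <- nchar(unlist(chars))
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned: unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  aligned_seqs(ids, unlist(chars, use.names = FALSE))
}

#' Construct an aligned-sequence set
#'
#' @param ids unique sequence identifiers.
#' @param seqs character vector of equal-length sequences over `A,C,G,T,N,-`.
#' @return An `aligned_seqs` object.
#' @export
aligned_seqs <- function(ids, seqs) {
  ids <- as.character(ids); seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and sequences differ in length")
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  lens <- nchar(seqs)
  if (length(seqs) == 0L || lens[1] == 0L) stop("empty alignment")
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  structure(list(ids = ids, seqs = seqs, length = lens[1]), class = "aligned_seqs")
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat(sprintf("aligned_seqs: %d sequences of length %d\n", length(x$ids), x$length))
  invisible(x)
}

#' Write aligned sequences as FASTA
#'
#' @param seqs an [aligned_seqs()] object.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "aligned_seqs"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0(">", seqs$ids, "\n", seqs$seqs), con)
  invisible(path)
}

#' Validate a genotype matrix and its metadata
#'
#' Computes the mean amplification rate (1 minus the fraction of missing
#' genotype calls), per-locus distinct allele counts, and reports -- without
#' raising -- metadata issues: ids not matching any genotyped individual,
#' out-of-range forearm (30--100 mm) or call-frequency (20--120 kHz) values,
#' unexpected sex codes.
#'
#' @param gm a [genotype_matrix()].
#' @param metadata optional data frame with a column `individual_id` and any
#'   of `sex` (`F`/`M`/`unknown`), `site`, `session`, `forearm_mm`, `fme_khz`.
#' @return A `validation_report` list: `n_individuals`, `n_loci`,
#'   `amplification_rate`, `per_locus_allele_counts`, `issues`.
#' @export
validate_dataset <- function(gm, metadata = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$ids); L <- length(gm$loci)
  miss <- gm$alleles[, , 1] == gm$missing_code
  amp <- 1 - sum(miss) / (n * L)
  counts <- vapply(seq_len(L), function(l) {
    a <- c(gm$alleles[, l, 1], gm$alleles[, l, 2])
    length(unique(a[a != gm$missing_code]))
  }, integer(1))
  names(counts) <- gm$loci
  issues <- character(0)
  if (!is.null(metadata)) {
    if (!"individual_id" %in% names(metadata))
      stop("metadata must contain an 'individual_id' column")
    extra <- setdiff(metadata$individual_id, gm$ids)
    if (length(extra) > 0L)
      issues <- c(issues, sprintf("metadata id '%s' matches no genotyped individual", extra))
    nometa <- setdiff(gm$ids, metadata$individual_id)
    if (length(nometa) > 0L)
      issues <- c(issues, sprintf("%d genotyped individuals without metadata", length(nometa)))
    if ("sex" %in% names(metadata)) {
      bad <- !metadata$sex %in% c("F", "M", "unknown") & !is.na(metadata$sex)
      if (any(bad)) issues <- c(issues, sprintf("unexpected sex code for id '%s'",
                                                metadata$individual_id[bad]))
    }
    rng <- list(forearm_mm = c(30, 100), fme_khz = c(20, 120))
    for (v in names(rng)) {
      if (v %in% names(metadata)) {
        x <- metadata[[v]]
        bad <- !is.na(x) & (x <= rng[[v]][1] | x >= rng[[v]][2])
        if (any(bad))
          issues <- c(issues, sprintf("%s out of range for id '%s'", v,
                                      metadata$individual_id[bad]))
      }
    }
  }
  structure(list(n_individuals = n, n_loci = L, amplification_rate = amp,
                 per_locus_allele_counts = counts, issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %d individuals, %d loci, amplification %.1f%%\n",
              x$n_individuals, x$n_loci, 100 * x$amplification_rate))
  cat(sprintf("  alleles per locus: %d-%d; %d issue(s)\n",
              min(x$per_locus_allele_counts), max(x$per_locus_allele_counts),
              length(x$issues)))
  invisible(x)
}
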