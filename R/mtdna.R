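# Raw pairwise distances on the barcode alignment, distance-threshold
# haplogrouping, and cyto-nuclear discordance accounting.

#' Raw (p-) pairwise distances with pairwise deletion
#'
#' The proportion of differing sites between each pair of sequences, counted
#' over the sites where both sequences carry an unambiguous base (A/C/G/T);
#' gaps, N and other ambiguity codes are deleted pairwise. A pair with no
#' comparable sites is NA (with a warning).
#'
#' @param seqs an [aligned_seqs()] object.
#' @return A `distance_matrix`: `ids`, `d` (symmetric matrix of fractions,
#'   zero diagonal), `sites_used` (pairwise comparable-site counts).
#' @export
raw_distance <- function(seqs) {
  stopifnot(inherits(seqs, "aligned_seqs"))
  n <- length(seqs$ids)
  chars <- do.call(rbind, strsplit(seqs$seqs, ""))
  # indicator crossproducts give per-pair match and comparable-site counts
  ok <- chars %in% c("A", "C", "G", "T")
  dim(ok) <- dim(chars)
  okm <- ok * 1
  comparable <- okm %*% t(okm)
  matches <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ib <- (chars == b & ok) * 1
    matches <- matches + ib %*% t(ib)
  }
  d <- (comparable - matches) / comparable  # exact: integer-valued counts
  d[comparable == 0] <- NA_real_
  diag(d) <- 0
  if (any(is.na(d[upper.tri(d)])))
    warning("some sequence pairs share no comparable sites")
  dimnames(d) <- dimnames(comparable) <- list(seqs$ids, seqs$ids)
  structure(list(ids = seqs$ids, d = d, sites_used = comparable),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  ut <- x$d[upper.tri(x$d)]
  cat(sprintf("distance_matrix: %d sequences; raw distance range %.4f-%.4f\n",
              length(x$ids), min(ut, na.rm = TRUE), max(ut, na.rm = TRUE)))
  invisible(x)
}

#' Haplogroup partition by single-linkage distance threshold
#'
#' Groups are the connected components of the graph joining sequence pairs
#' at raw distance <= `cutoff` (single linkage). The default cutoff of 0.02
#' sits an order of magnitude above typical within-haplogroup barcode
#' diversity and well below between-species divergence; lowering the cutoff
#' can only split groups, never merge them.
#'
#' @param dm a [raw_distance()] result.
#' @param cutoff distance threshold in (0, 1).
#' @return A `haplogroup_partition`: `groups` (integer label per sequence,
#'   numbered by first occurrence), `cutoff`, `within_means` (per group),
#'   `between_mean`.
#' @export
haplogroup_partition <- function(dm, cutoff = 0.02) {
  stopifnot(inherits(dm, "distance_matrix"))
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  n <- length(dm$ids)
  adj <- !is.na(dm$d) & dm$d <= cutoff
  lab <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (lab[i] > 0L) next
    nxt <- nxt + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      if (lab[v] > 0L) next
      lab[v] <- nxt
      queue <- c(queue, which(adj[v, ] & lab == 0L))
    }
  }
  within <- vapply(seq_len(nxt), function(g) {
    idx <- which(lab == g)
    if (length(idx) < 2L) return(NA_real_)
    mean(dm$d[idx, idx][upper.tri(dm$d[idx, idx])], na.rm = TRUE)
  }, numeric(1))
  between <- if (nxt > 1L) {
    diffg <- outer(lab, lab, `!=`)
    mean(dm$d[diffg & upper.tri(dm$d)], na.rm = TRUE)
  } else NA_real_
  structure(list(groups = stats::setNames(lab, dm$ids), cutoff = cutoff,
                 within_means = within, between_mean = between),
            class = "haplogroup_partition")
}

#' @export
print.haplogroup_partition <- function(x, ...) {
  cat(sprintf("haplogroup_partition: %d group(s) at cutoff %.3f; within %s; between %s\n",
              max(x$groups), x$cutoff,
              paste(sprintf("%.4f", x$within_means), collapse = "/"),
              ifelse(is.na(x$between_mean), "NA", sprintf("%.4f", x$between_mean))))
  invisible(x)
}

#' Cyto-nuclear discordance table
#'
#' Cross-tabulates nuclear cluster labels against mitochondrial haplogroup
#' labels over the individuals carrying both, and reports the per-direction
#' discordance proportions. In the two-by-two case, asymmetric introgression
#' is flagged when exactly one off-diagonal cell is non-zero.
#'
#' @param nuclear named vector of nuclear labels (names = individual ids).
#' @param mt named vector of mitochondrial labels.
#' @return A `discordance_table`: `counts` (nuclear x mt), `proportions`
#'   (per nuclear label, fraction of discordant mt), `asymmetric` flag,
#'   `n`.
#' @export
cytonuclear_discordance <- function(nuclear, mt) {
  shared <- intersect(names(nuclear), names(mt))
  if (length(shared) == 0L) stop("nuclear and mitochondrial label sets share no ids")
  nu <- as.character(nuclear[shared]); mi <- as.character(mt[shared])
  levs <- sort(unique(c(nu, mi)))
  counts <- table(factor(nu, levels = levs), factor(mi, levels = levs),
                  dnn = c("nuclear", "mt"))
  prop <- vapply(levs, function(l) {
    sel <- nu == l
    if (!any(sel)) return(NA_real_)
    mean(mi[sel] != l)
  }, numeric(1))
  asym <- FALSE
  if (length(levs) == 2L) {
    off <- c(counts[1, 2], counts[2, 1])
    asym <- sum(off > 0) == 1L
  }
  structure(list(counts = counts, proportions = prop, asymmetric = asym,
                 n = length(shared)),
            class = "discordance_table")
}

#' @export
print.discordance_table <- function(x, ...) {
  print(x$counts)
  cat(sprintf("discordance proportions: %s%s\n",
              paste(sprintf("%s=%.3f", names(x$proportions), x$proportions),
                    collapse = ", "),
              if (x$asymmetric) " (asymmetric)" else ""))
  invisible(x)
}
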