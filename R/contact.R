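## Unitig-level contact matrices: quantify the share of inter-unitig
## contacts joining allelic unitigs and demonstrate the pruning effect
## via a simple deterministic contact-graph grouping (a transparent proxy
## for scaffolder behaviour, not a scaffolder).

#' Build a unitig-level contact matrix from Hi-C pairs
#'
#' `counts[i, j]` is the number of pairs joining unitigs i and j
#' (symmetric); the diagonal holds intra-unitig pair counts. Pairs
#' touching unitigs absent from the length table are skipped and tallied
#' in the `n_unknown` element.
#'
#' @param pairs contact-pair data.frame.
#' @param unitig_lengths named numeric vector of unitig lengths (bp);
#'   its names fix the matrix dimension order.
#' @return an object of class `contact_matrix` with elements `ids`,
#'   `counts`, `lengths`, `normalization`, `n_unknown`.
#' @export
build_contact_matrix <- function(pairs, unitig_lengths) {
  ids <- names(unitig_lengths)
  if (is.null(ids)) stop("unitig_lengths must be named", call. = FALSE)
  known <- pairs$uid1 %in% ids & pairs$uid2 %in% ids
  n_unknown <- sum(!known)
  if (n_unknown > 0L) {
    warning(n_unknown, " pair(s) reference unitigs without lengths; skipped")
  }
  p <- pairs[known, , drop = FALSE]
  f1 <- factor(pmin(p$uid1, p$uid2), levels = ids)
  f2 <- factor(pmax(p$uid1, p$uid2), levels = ids)
  upper <- table(f1, f2)
  counts <- unclass(upper) + t(unclass(upper))
  diag(counts) <- diag(unclass(upper))
  dimnames(counts) <- list(ids, ids)
  structure(list(ids = ids, counts = counts,
                 lengths = unname(unitig_lengths),
                 normalization = "none", n_unknown = n_unknown),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  off <- sum(x$counts) - sum(diag(x$counts))
  cat("Contact matrix:", length(x$ids), "unitigs;",
      off / 2, "inter-unitig pairs;", sum(diag(x$counts)),
      "intra-unitig pairs\n")
  invisible(x)
}

#' Fraction of inter-unitig contacts joining allelic unitigs
#'
#' Sum of contact counts over allelic unitig pairs divided by the sum
#' over all inter-unitig pairs; 0 when there are no inter-unitig
#' contacts. After pruning with a fully marker-covered allelic table this
#' fraction is exactly 0.
#'
#' @param matrix a `contact_matrix`.
#' @param table an `allelic_table`.
#' @return a number in \[0, 1\].
#' @export
inter_allelic_fraction <- function(matrix, table) {
  stopifnot(inherits(matrix, "contact_matrix"),
            inherits(table, "allelic_table"))
  total <- (sum(matrix$counts) - sum(diag(matrix$counts))) / 2
  if (total == 0) return(0)
  ap <- table$allelic_pairs
  keep <- ap$u1 %in% matrix$ids & ap$u2 %in% matrix$ids
  ap <- ap[keep, , drop = FALSE]
  if (nrow(ap) == 0L) return(0)
  num <- sum(matrix$counts[cbind(ap$u1, ap$u2)])
  num / total
}

#' Group unitigs by contact similarity
#'
#' Deterministic average-linkage agglomerative clustering on the
#' length-normalized contact similarity `counts[i, j] / (len_i * len_j)`,
#' cut into `k` groups. Unitig ids are sorted lexicographically before
#' clustering so equal-similarity ties break identically across
#' platforms; singleton groups are allowed.
#'
#' @param matrix a `contact_matrix`.
#' @param k target number of groups.
#' @return named integer vector mapping unitig id to group label.
#' @export
group_unitigs <- function(matrix, k) {
  stopifnot(inherits(matrix, "contact_matrix"))
  n <- length(matrix$ids)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n) {
    stop("k must be between 1 and the number of unitigs", call. = FALSE)
  }
  ord <- order(matrix$ids)
  ids <- matrix$ids[ord]
  cnt <- matrix$counts[ord, ord, drop = FALSE]
  len <- matrix$lengths[ord]
  sim <- cnt / outer(len, len)
  diag(sim) <- 0
  mx <- max(sim)
  d <- if (mx > 0) 1 - sim / mx else matrix(1, n, n)
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  if (n == 1L) return(setNames(1L, ids))
  hc <- hclust(as.dist(d), method = "average")
  cutree(hc, k = k)
}

#' Pair-counting agreement between two groupings (adjusted Rand index)
#'
#' Chance-corrected agreement over pairs of items: 1 for identical
#' partitions, ~0 for independent ones. Used to score contact-graph
#' groups against the true chromosome of origin.
#'
#' @param a,b label vectors over the same items (matched by name when
#'   both are named).
#' @return a number <= 1.
#' @export
pair_agreement <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

#' Export a contact matrix as sparse TSV
#'
#' Three columns (`uid_i`, `uid_j`, `count`) with `uid_i <= uid_j`; zero
#' cells omitted.
#'
#' @param matrix a `contact_matrix`.
#' @param path output path.
#' @export
write_contact_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "contact_matrix"))
  idx <- which(upper.tri(matrix$counts, diag = TRUE) & matrix$counts > 0,
               arr.ind = TRUE)
  i <- matrix$ids[idx[, 1L]]
  j <- matrix$ids[idx[, 2L]]
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  cnt <- matrix$counts[idx]
  ord <- order(i, j)
  writeLines(paste(i[ord], j[ord], cnt[ord], sep = "\t"), path)
  invisible(path)
}
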