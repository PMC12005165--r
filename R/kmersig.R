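## K-mer signatures per chromosome: canonical k-mer sketches with
## optional scaled subsampling, pairwise similarity in composition
## (presence/absence Jaccard) and frequency (abundance-weighted cosine)
## modes, average-linkage clustering, and the strict-cut subgenome
## cluster validity criterion.

#' Sketch the canonical k-mers of one sequence
#'
#' K-mers containing non-ACGT symbols are skipped; each remaining k-mer
#' is represented by the lexicographic minimum of itself and its reverse
#' complement and hashed with a fixed 64-bit non-cryptographic hash.
#' With `scaled > 1` only the fraction `1/scaled` of hash space is
#' retained (a minhash-style subsample); abundances are accumulated over
#' retained k-mers.
#'
#' @param sequence a single sequence: character string, `DNAString`, or
#'   a length-1 `DNAStringSet`.
#' @param k k-mer size (>= 3).
#' @param scaled subsampling factor (1 retains all k-mers).
#' @param id source identifier stored in the signature (defaults to the
#'   sequence name, if any).
#' @return an object of class `kmer_signature`: list with `source_id`,
#'   `k`, `scaled`, `hashes` (sorted numeric), `counts` (aligned
#'   integer abundances).
#' @export
sketch <- function(sequence, k, scaled = 1L, id = NULL) {
  if (methods::is(sequence, "XStringSet")) {
    if (length(sequence) != 1L) stop("sketch() takes one sequence",
                                     call. = FALSE)
    if (is.null(id)) id <- names(sequence)
    sequence <- as.character(sequence[[1L]])
  } else if (methods::is(sequence, "XString")) {
    sequence <- as.character(sequence)
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  assert_scalar_number(k, "k", min = 3)
  assert_scalar_number(scaled, "scaled", min = 1)
  if (is.null(id)) id <- "seq"
  if (k > nchar(sequence)) {
    warning("k = ", k, " exceeds sequence length ", nchar(sequence),
            "; empty signature")
    res <- list(hash = numeric(), count = integer())
  } else {
    res <- .sketch_cpp(sequence, as.integer(k), as.numeric(scaled))
  }
  structure(list(source_id = id, k = as.integer(k),
                 scaled = as.integer(scaled), hashes = res$hash,
                 counts = res$count),
            class = "kmer_signature")
}

#' Sketch every sequence in a set
#'
#' @param sequences a `DNAStringSet` or named character vector.
#' @inheritParams sketch
#' @return named list of `kmer_signature` objects.
#' @export
sketch_set <- function(sequences, k, scaled = 1L) {
  seqs <- as_seq_chr(sequences)
  out <- lapply(names(seqs), function(id) {
    sketch(seqs[[id]], k = k, scaled = scaled, id = id)
  })
  names(out) <- names(seqs)
  out
}

#' @export
print.kmer_signature <- function(x, ...) {
  cat("Kmer signature '", x$source_id, "': k=", x$k, ", scaled=",
      x$scaled, ", ", length(x$hashes), " kmers\n", sep = "")
  invisible(x)
}

#' Similarity between two k-mer signatures
#'
#' Composition mode is the Jaccard index of the k-mer sets (0 when both
#' are empty); frequency mode is the cosine similarity of the abundance
#' vectors over the union of k-mers.
#'
#' @param a,b `kmer_signature` objects with equal `k` and `scaled`.
#' @param mode `"composition"` or `"frequency"`.
#' @return a number in \[0, 1\].
#' @export
similarity <- function(a, b, mode = c("composition", "frequency")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "kmer_signature"), inherits(b, "kmer_signature"))
  if (a$k != b$k) stop("k mismatch: ", a$k, " vs ", b$k, call. = FALSE)
  if (a$scaled != b$scaled) {
    stop("scaled mismatch: ", a$scaled, " vs ", b$scaled, call. = FALSE)
  }
  if (length(a$hashes) == 0L && length(b$hashes) == 0L) return(0)
  if (mode == "composition") {
    ninter <- sum(a$hashes %in% b$hashes)
    nunion <- length(a$hashes) + length(b$hashes) - ninter
    if (nunion == 0L) return(0)
    return(ninter / nunion)
  }
  ia <- match(a$hashes, b$hashes)
  dot <- sum(as.numeric(a$counts[!is.na(ia)]) *
               as.numeric(b$counts[ia[!is.na(ia)]]))
  na <- sqrt(sum(as.numeric(a$counts)^2))
  nb <- sqrt(sum(as.numeric(b$counts)^2))
  if (na == 0 || nb == 0) return(0)
  dot / (na * nb)
}

#' Pairwise similarity matrix over signatures
#'
#' @param signatures list of `kmer_signature` objects.
#' @inheritParams similarity
#' @return an object of class `similarity_matrix`: list with `ids`,
#'   `values` (symmetric matrix, unit diagonal), `mode`, `k`.
#' @export
similarity_matrix <- function(signatures,
                              mode = c("composition", "frequency")) {
  mode <- match.arg(mode)
  ids <- vapply(signatures, `[[`, "", "source_id")
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicate signature ids", call. = FALSE)
  values <- diag(nrow = n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        v <- similarity(signatures[[i]], signatures[[j]], mode)
        values[i, j] <- v
        values[j, i] <- v
      }
    }
  }
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, mode = mode,
                 k = signatures[[1L]]$k),
            class = "similarity_matrix")
}

#' Average-linkage clustering of a similarity matrix
#'
#' Agglomerative clustering on distance `1 - similarity`. Ids are sorted
#' lexicographically before clustering so equal-distance ties break
#' identically across platforms.
#'
#' @param matrix a `similarity_matrix`.
#' @return an [stats::hclust] object (merge list with heights).
#' @export
cluster_signatures <- function(matrix) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  if (length(matrix$ids) < 2L) stop(">= 2 signatures required",
                                    call. = FALSE)
  ord <- order(matrix$ids)
  d <- 1 - matrix$values[ord, ord]
  hclust(as.dist(d), method = "average")
}

#' Strict-cut subgenome cluster validity check
#'
#' Cuts the dendrogram into `n_subgenomes` clusters and passes iff every
#' subgenome's chromosomes fall within a single cluster (a cluster may
#' contain several whole subgenomes, but no subgenome may be split).
#'
#' @param dendrogram an `hclust` object over labelled leaves.
#' @param labels named character vector mapping leaf id to subgenome.
#' @param n_subgenomes number of clusters to cut.
#' @return list with `pass` (logical), `offenders` (ids of every split
#'   subgenome's chromosomes), `assignment` (cluster index per leaf).
#' @export
strict_cut_check <- function(dendrogram, labels, n_subgenomes) {
  stopifnot(inherits(dendrogram, "hclust"))
  leaves <- dendrogram$labels
  if (n_subgenomes > length(leaves)) {
    stop("n_subgenomes exceeds leaf count", call. = FALSE)
  }
  if (!all(leaves %in% names(labels))) {
    stop("every leaf must be labelled", call. = FALSE)
  }
  cl <- cutree(dendrogram, k = n_subgenomes)
  sub <- labels[leaves]
  split_subs <- names(which(tapply(cl[leaves], sub,
                                   function(x) length(unique(x))) > 1L))
  offenders <- leaves[sub %in% split_subs]
  list(pass = length(split_subs) == 0L, offenders = offenders,
       assignment = cl)
}

#' Serialize a signature as JSON
#'
#' @param signature a `kmer_signature`.
#' @param path output path.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "kmer_signature"))
  obj <- list(source_id = signature$source_id, k = signature$k,
              scaled = signature$scaled, hashes = signature$hashes,
              counts = signature$counts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature written by [write_signature()]
#'
#' @param path path to a signature JSON file.
#' @return a `kmer_signature`.
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(source_id = obj$source_id, k = as.integer(obj$k),
                 scaled = as.integer(obj$scaled),
                 hashes = as.numeric(obj$hashes),
                 counts = as.integer(obj$counts)),
            class = "kmer_signature")
}

#' Export a similarity matrix as TSV
#'
#' @param matrix a `similarity_matrix`.
#' @param path output path.
#' @export
write_similarity_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  df <- as.data.frame(matrix$values)
  df <- cbind(id = matrix$ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The k-mer size ladder used for signature comparisons
#'
#' Odd sizes 3 to 21 in steps of 2, then 21 to 161 in steps of 10.
#'
#' @return integer vector of k-mer sizes.
#' @export
kmer_ladder <- function() {
  unique(c(seq(3L, 21L, by = 2L), seq(21L, 161L, by = 10L)))
}
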