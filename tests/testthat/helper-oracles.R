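## Independent brute-force oracles used across the suite. Each oracle
## recomputes a quantity by direct enumeration, never through the code
## path it checks.

## all k-mers of a sequence as strings, canonicalized against the
## reverse complement, windows with non-ACGT skipped
oracle_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (k > n) return(character())
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  ok <- !grepl("[^ACGT]", kmers)
  kmers <- kmers[ok]
  if (length(kmers) == 0L) return(character())
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  pmin(kmers, rc)
}

oracle_jaccard <- function(s1, s2, k) {
  a <- unique(oracle_kmers(s1, k))
  b <- unique(oracle_kmers(s2, k))
  if (length(a) == 0L && length(b) == 0L) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

oracle_cosine <- function(s1, s2, k) {
  ta <- table(oracle_kmers(s1, k))
  tb <- table(oracle_kmers(s2, k))
  all_k <- union(names(ta), names(tb))
  va <- as.numeric(ta[all_k]); va[is.na(va)] <- 0
  vb <- as.numeric(tb[all_k]); vb[is.na(vb)] <- 0
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}

## per-base pileup depth, then window means
oracle_windowed_depth <- function(aln, len, window) {
  depth <- numeric(len)
  for (i in seq_len(nrow(aln))) {
    s <- max(aln$target_start[i], 0L) + 1L
    e <- min(aln$target_end[i], len)
    if (e >= s) depth[s:e] <- depth[s:e] + 1
  }
  starts <- seq(0L, len - 1L, by = window)
  ends <- pmin(starts + window, len)
  vapply(seq_along(starts),
         function(j) mean(depth[(starts[j] + 1L):ends[j]]), 0.0)
}

## naive sliding scan for motif + reverse complement start positions
oracle_motif_starts <- function(seq, motif) {
  seq <- toupper(seq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  w <- nchar(motif)
  hits <- integer()
  for (p in seq_len(nchar(seq) - w + 1L)) {
    sub <- substr(seq, p, p + w - 1L)
    if (sub == motif || sub == rc) hits <- c(hits, p - 1L)
  }
  hits
}

## maximal N-runs by run-length encoding on characters
oracle_gaps <- function(seq, min_run) {
  r <- rle(strsplit(toupper(seq), "")[[1L]] == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep])
}

## single-pass classification of every pair against the three filters
oracle_prune_class <- function(pairs, allelic_pairs, mask = 2304L,
                               min_mapq = 30L) {
  key <- paste(pmin(pairs$uid1, pairs$uid2),
               pmax(pairs$uid1, pairs$uid2))
  akey <- paste(pmin(allelic_pairs$u1, allelic_pairs$u2),
                pmax(allelic_pairs$u1, allelic_pairs$u2))
  flagfail <- bitwAnd(pairs$flags1, mask) != 0L |
    bitwAnd(pairs$flags2, mask) != 0L
  mapqfail <- pmin(pairs$mapq1, pairs$mapq2) < min_mapq
  allelic <- pairs$uid1 != pairs$uid2 & key %in% akey
  cls <- rep("keep", nrow(pairs))
  cls[allelic] <- "allelic"
  cls[mapqfail] <- "mapq"
  cls[flagfail] <- "flag"
  cls
}

## random contact-pair stream over a small unitig namespace
random_pairs <- function(n, unitigs = paste0("u", 1:6), seed = 1) {
  set.seed(seed)
  data.frame(read_id = sprintf("r%04d", seq_len(n)),
             uid1 = sample(unitigs, n, replace = TRUE),
             pos1 = sample.int(1000L, n, replace = TRUE) - 1L,
             mapq1 = sample(0:60, n, replace = TRUE),
             flags1 = sample(c(0L, 16L, 256L, 2048L), n, replace = TRUE),
             uid2 = sample(unitigs, n, replace = TRUE),
             pos2 = sample.int(1000L, n, replace = TRUE) - 1L,
             mapq2 = sample(0:60, n, replace = TRUE),
             flags2 = sample(c(0L, 16L, 256L, 2048L), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## cached simulations so expensive fixtures are built once per run
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed, events = TRUE, ...) {
  key <- paste0("s", seed, "_", events, "_",
                paste(deparse(list(...)), collapse = ""))
  if (!exists(key, envir = .sim_cache)) {
    cfg <- sim_config(seed = seed, planted_exchange = events,
                      planted_translocation = events, ...)
    assign(key, simulate_allotetraploid(cfg), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}
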