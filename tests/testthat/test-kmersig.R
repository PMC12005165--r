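test_that("sketching canonicalizes against the reverse complement", {
  ## ACGT at k=3: ACG and CGT are reverse complements -> one canonical
  ## k-mer with abundance 2
  sig <- sketch("ACGT", k = 3)
  expect_equal(length(sig$hashes), 1L)
  expect_equal(sig$counts, 2L)

  sig <- sketch(strrep("N", 50), k = 5)
  expect_equal(length(sig$hashes), 0L)

  expect_warning(sig <- sketch("ACG", k = 10), "exceeds")
  expect_equal(length(sig$hashes), 0L)
})

test_that("scaled subsampling retains a subset of the full sketch", {
  s <- random_dna(2000, seed = 5)
  full <- sketch(s, k = 15, scaled = 1)
  sub <- sketch(s, k = 15, scaled = 10)
  expect_true(all(sub$hashes %in% full$hashes))
  expect_lt(length(sub$hashes), length(full$hashes))
  ## retained abundances agree with the full sketch
  expect_equal(sub$counts,
               full$counts[match(sub$hashes, full$hashes)])
})

test_that("sketch abundances equal direct k-mer enumeration", {
  for (seed in 1:5) {
    s <- random_dna(300, seed = seed)
    k <- c(5L, 7L, 11L)[seed %% 3 + 1]
    sig <- sketch(s, k = k)
    counts <- table(oracle_kmers(s, k))
    expect_equal(length(sig$hashes), length(counts))
    expect_equal(sort(as.integer(sig$counts)),
                 sort(as.integer(counts)))
  }
})

test_that("similarity endpoints: identity is 1, disjoint is 0", {
  a <- sketch(random_dna(500, 1), k = 11, id = "a")
  expect_equal(similarity(a, a, "composition"), 1.0)
  expect_equal(similarity(a, a, "frequency"), 1.0)

  b <- sketch(random_dna(500, 2), k = 21, id = "b")
  expect_error(similarity(a, b), "k mismatch")

  ## disjoint sets (no shared 21-mers between random 500-mers)
  a21 <- sketch(random_dna(500, 1), k = 21)
  b21 <- sketch(random_dna(500, 2), k = 21)
  expect_equal(similarity(a21, b21, "composition"), 0.0)
  expect_equal(similarity(a21, b21, "frequency"), 0.0)

  e1 <- suppressWarnings(sketch("A", k = 5))
  e2 <- suppressWarnings(sketch("C", k = 5))
  expect_equal(similarity(e1, e2, "composition"), 0)
})

test_that("similarity equals full-enumeration Jaccard and cosine", {
  for (seed in 1:5) {
    s1 <- random_dna(1000, seed = 100 + seed)
    s2 <- paste0(substr(s1, 1, 600), random_dna(400, seed = 200 + seed))
    k <- 7L
    a <- sketch(s1, k = k, id = "a")
    b <- sketch(s2, k = k, id = "b")
    expect_equal(similarity(a, b, "composition"),
                 oracle_jaccard(s1, s2, k), tolerance = 1e-12)
    expect_equal(similarity(a, b, "frequency"),
                 oracle_cosine(s1, s2, k), tolerance = 1e-12)
  }
})

test_that("similarity matrix is symmetric with a unit diagonal", {
  seqs <- setNames(vapply(1:4, function(i) random_dna(400, i), ""),
                   paste0("s", 1:4))
  sigs <- sketch_set(seqs, k = 9)
  for (mode in c("composition", "frequency")) {
    sm <- similarity_matrix(sigs, mode)
    expect_equal(diag(sm$values), rep(1, 4), ignore_attr = TRUE)
    expect_true(isSymmetric(sm$values))
    expect_true(all(sm$values >= 0 & sm$values <= 1))
  }
})

test_that("clustering merges by similarity with deterministic ties", {
  v <- diag(4)
  ids <- c("a1", "a2", "b1", "b2")
  dimnames(v) <- list(ids, ids)
  v["a1", "a2"] <- v["a2", "a1"] <- 0.9
  v["b1", "b2"] <- v["b2", "b1"] <- 0.8
  sm <- structure(list(ids = ids, values = v, mode = "composition",
                       k = 9L), class = "similarity_matrix")
  hc <- cluster_signatures(sm)
  cl <- cutree(hc, 2)
  expect_equal(unname(cl[c("a1", "a2")]), rep(cl[["a1"]], 2))
  expect_equal(unname(cl[c("b1", "b2")]), rep(cl[["b1"]], 2))

  two <- structure(list(ids = c("x", "y"),
                        values = matrix(c(1, .4, .4, 1), 2,
                                        dimnames = list(c("x", "y"),
                                                        c("x", "y"))),
                        mode = "composition", k = 9L),
                   class = "similarity_matrix")
  hc2 <- cluster_signatures(two)
  expect_equal(hc2$height, 0.6)
  expect_error(cluster_signatures(
    structure(list(ids = "x", values = matrix(1)),
              class = "similarity_matrix")), ">= 2")
})

test_that("average-linkage merge heights match an exhaustive oracle", {
  ## brute-force average linkage over 8 leaves
  set.seed(77)
  n <- 8
  ids <- sprintf("L%02d", 1:n)
  d <- matrix(runif(n * n), n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  sm <- structure(list(ids = ids, values = 1 - d, mode = "composition",
                       k = 9L), class = "similarity_matrix")
  hc <- cluster_signatures(sm)

  ## oracle: explicit agglomeration tracking average inter-cluster
  ## distances over the original matrix
  clusters <- as.list(ids)
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(hc$height, heights, tolerance = 1e-12)
})

test_that("strict cut passes iff no subgenome is split", {
  v <- diag(4)
  ids <- c("a1", "a2", "b1", "b2")
  dimnames(v) <- list(ids, ids)
  v["a1", "a2"] <- v["a2", "a1"] <- 0.9
  v["b1", "b2"] <- v["b2", "b1"] <- 0.9
  sm <- structure(list(ids = ids, values = v, mode = "composition",
                       k = 9L), class = "similarity_matrix")
  hc <- cluster_signatures(sm)
  labels <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b")
  expect_true(strict_cut_check(hc, labels, 2)$pass)

  ## one b leaf attached to the a block splits subgenome b
  v2 <- diag(4)
  dimnames(v2) <- list(ids, ids)
  v2["a1", "b1"] <- v2["b1", "a1"] <- 0.9
  v2["a1", "a2"] <- v2["a2", "a1"] <- 0.85
  v2["b2", "b2"] <- 1
  sm2 <- structure(list(ids = ids, values = v2, mode = "composition",
                        k = 9L), class = "similarity_matrix")
  hc2 <- cluster_signatures(sm2)
  res <- strict_cut_check(hc2, labels, 2)
  expect_false(res$pass)
  expect_true(all(c("b1", "b2") %in% res$offenders))

  expect_error(strict_cut_check(hc, labels, 5), "leaf count")
})

test_that("frequency mode separates subgenomes; composition pairs homologues", {
  sim <- cached_sim(1, events = TRUE)
  labs <- setNames(sim$truth$haplotype_of$subgenome,
                   sim$truth$haplotype_of$seq_id)
  sigs <- sketch_set(sim$genome, k = 81)
  freq <- strict_cut_check(
    cluster_signatures(similarity_matrix(sigs, "frequency")), labs, 2)
  expect_true(freq$pass)
  comp_hc <- cluster_signatures(similarity_matrix(sigs, "composition"))
  comp <- strict_cut_check(comp_hc, labs, 2)
  expect_false(comp$pass)
  ## composition clusters homologous pairs: each haplotype pair of one
  ## chromosome merges before anything else joins it
  cl4 <- cutree(comp_hc, 4)
  meta <- sim$truth$haplotype_of
  pair_of <- split(meta$seq_id,
                   paste(meta$base_chromosome, meta$subgenome))
  for (p in pair_of) {
    expect_equal(length(unique(cl4[p])), 1L)
  }
})

test_that("signatures round-trip through JSON", {
  sig <- sketch(random_dna(300, 3), k = 9, id = "chrX")
  f <- withr::local_tempfile()
  write_signature(sig, f)
  back <- read_signature(f)
  expect_equal(back$source_id, "chrX")
  expect_equal(back$hashes, sig$hashes)
  expect_equal(back$counts, sig$counts)
})

test_that("the reporting k ladder matches the published grid", {
  kl <- kmer_ladder()
  expect_equal(kl[1:10], seq(3L, 21L, by = 2L))
  expect_equal(kl[kl > 21], seq(31L, 161L, by = 10L))
  expect_equal(sum(kl == 21L), 1L)
})
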