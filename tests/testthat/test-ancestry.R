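aln_df <- function(target, start, end, query = NULL) {
  n <- length(start)
  data.frame(query_id = if (is.null(query)) sprintf("r%03d", seq_len(n))
             else query,
             target_id = rep(target, length.out = n),
             target_start = as.integer(start),
             target_end = as.integer(end), mapq = rep(60L, n),
             flags = rep(0L, n), stringsAsFactors = FALSE)
}

test_that("windowed depth equals overlap mass over window size", {
  tr <- windowed_depth(aln_df("t", 0, 100), c(t = 100), window = 50)
  expect_equal(tr$depth, c(1, 1))
  expect_equal(tr$start, c(0L, 50L))

  tr <- windowed_depth(aln_df("t", integer(), integer()), c(t = 100),
                       window = 30)
  expect_equal(tr$depth, rep(0, 4))
  ## final short window uses its true size
  expect_equal(tr$end[4], 100L)

  expect_warning(windowed_depth(aln_df("zz", 0, 10), c(t = 100), 50),
                 "unknown")
})

test_that("windowed depth equals a per-base pileup oracle", {
  set.seed(31)
  for (i in 1:5) {
    len <- sample(200:400, 1)
    n <- 20
    s <- sample(0:(len - 20), n, replace = TRUE)
    e <- pmin(s + sample(10:80, n, replace = TRUE), len)
    a <- aln_df("t", s, e)
    w <- sample(c(25, 40, 64), 1)
    tr <- windowed_depth(a, c(t = len), window = w)
    expect_equal(tr$depth, oracle_windowed_depth(a, len, w))
  }
})

test_that("depth conservation: window mass sums to total aligned bases", {
  set.seed(7)
  len <- 500
  s <- sample(0:450, 30, replace = TRUE)
  e <- pmin(s + sample(5:60, 30, replace = TRUE), len)
  a <- aln_df("t", s, e)
  tr <- windowed_depth(a, c(t = len), window = 64)
  expect_equal(sum(tr$depth * (tr$end - tr$start)), sum(e - s))
})

test_that("per-source normalization brings on-target depth to about 1", {
  tr <- data.frame(target_id = "t", start = 0:9 * 10, end = 1:10 * 10,
                   depth = 30, source = "s1")
  out <- normalize_tracks(tr)
  expect_equal(out$depth, rep(1, 10))

  ## two sources covering their own halves at different raw depths
  tr2 <- rbind(data.frame(target_id = "a", start = 0:4 * 10,
                          end = 1:5 * 10, depth = 10, source = "x"),
               data.frame(target_id = "b", start = 0:4 * 10,
                          end = 1:5 * 10, depth = 0, source = "x"),
               data.frame(target_id = "a", start = 0:4 * 10,
                          end = 1:5 * 10, depth = 0, source = "y"),
               data.frame(target_id = "b", start = 0:4 * 10,
                          end = 1:5 * 10, depth = 40, source = "y"))
  out <- normalize_tracks(tr2)
  expect_equal(out$depth[out$source == "x" & out$target_id == "a"],
               rep(1, 5))
  expect_equal(out$depth[out$source == "y" & out$target_id == "b"],
               rep(1, 5))

  tr3 <- tr; tr3$depth <- 0
  expect_error(normalize_tracks(tr3), "s1")
})

test_that("normalized on-target windows centre on 1 under simulated noise", {
  sim <- cached_sim(1, events = TRUE)
  truth <- sim$truth
  lens <- setNames(truth$haplotype_of$length, truth$haplotype_of$seq_id)
  tr <- normalize_tracks(depth_tracks(sim$progenitor_alignments, lens,
                                      window = 10000))
  briz <- tr[tr$source == "brizantha", ]
  on_target <- truth$haplotype_of$seq_id[truth$haplotype_of$subgenome == "B"]
  on_target <- setdiff(on_target, truth$event_intervals$target_id)
  med <- median(briz$depth[briz$target_id %in% on_target])
  expect_lt(abs(med - 1), 0.05)
})

test_that("subgenome assignment applies the margin and combined-label rules", {
  grid <- data.frame(target_id = "t", start = 0:9 * 10, end = 1:10 * 10)
  mk <- function(dA, dB, dC = NULL) {
    tr <- rbind(cbind(grid, depth = dA, source = "a"),
                cbind(grid, depth = dB, source = "b"))
    if (!is.null(dC)) tr <- rbind(tr, cbind(grid, depth = dC, source = "c"))
    tr
  }
  expect_equal(assign_subgenomes(mk(1.0, 0.05))$assigned_source, "a")
  expect_equal(assign_subgenomes(mk(1.0, 1.0))$assigned_source, "ambiguous")
  ## two indistinguishable sources jointly above a third
  expect_equal(assign_subgenomes(mk(1.0, 1.0, 0.05))$assigned_source, "a+b")
  ## margin reported relative to the best outsider
  expect_equal(assign_subgenomes(mk(1.0, 0.05, 0.02))$margin, 20)
})

test_that("assignment is invariant to rescaling one source's raw depths", {
  sim <- cached_sim(1, events = TRUE)
  truth <- sim$truth
  lens <- setNames(truth$haplotype_of$length, truth$haplotype_of$seq_id)
  raw <- depth_tracks(sim$progenitor_alignments, lens, window = 10000)
  scaled <- raw
  i <- scaled$source == "brizantha"
  scaled$depth[i] <- scaled$depth[i] * 7.3
  c1 <- assign_subgenomes(normalize_tracks(raw))
  c2 <- assign_subgenomes(normalize_tracks(scaled))
  expect_equal(c2$assigned_source, c1$assigned_source)
})

test_that("switch detection smooths short runs and tiles each target", {
  grid <- data.frame(target_id = "t", start = 0:49 * 10, end = 1:50 * 10)
  const <- rbind(cbind(grid, depth = 1.0, source = "a"),
                 cbind(grid, depth = 0.1, source = "b"))
  segs <- detect_switches(const, min_segment = 5)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start, 0L)
  expect_equal(segs$end, 500L)
  expect_equal(segs$dominant_source, "a")
  expect_equal(length(flagged_targets(segs)), 0L)

  ## clean flip at the midpoint lands exactly on the window edge
  flip <- rbind(cbind(grid, depth = rep(c(1.0, 0.1), each = 25),
                      source = "a"),
                cbind(grid, depth = rep(c(0.1, 1.0), each = 25),
                      source = "b"))
  segs <- detect_switches(flip, min_segment = 5)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$end[1], 250L)
  expect_equal(flagged_targets(segs), "t")

  ## a 2-window blip is absorbed by the flanking majority
  blip <- flip
  blip$depth[blip$source == "a"][10:11] <- 0.01
  segs <- detect_switches(blip, min_segment = 5)
  expect_equal(nrow(segs), 2L)
})

test_that("planted exchange boundaries recover within two windows under noise", {
  window <- 100000
  L <- 10e6
  nw <- L / window
  true_start <- 5e6
  errs <- numeric()
  for (seed in 1:10) {
    set.seed(seed * 17)
    grid <- data.frame(target_id = "t", start = (0:(nw - 1)) * window,
                       end = (1:nw) * window)
    base_a <- ifelse(grid$start >= true_start, 0.1, 1.0)
    noise <- function(n) exp(rnorm(n, 0, 0.3))
    tr <- rbind(cbind(grid, depth = base_a * noise(nw), source = "a"),
                cbind(grid, depth = (1.1 - base_a) * noise(nw),
                      source = "b"))
    segs <- detect_switches(tr, min_segment = 10)
    bnd <- segs$end[segs$dominant_source == "a" & segs$start == 0]
    errs <- c(errs, abs(bnd - true_start) / window)
  }
  expect_lte(max(errs), 2)
})

test_that("full ancestry recovery on the simulated tetraploid", {
  ok <- TRUE
  for (s in 1:3) {
    sim <- cached_sim(s, events = TRUE)
    truth <- sim$truth
    lens <- setNames(truth$haplotype_of$length, truth$haplotype_of$seq_id)
    tr <- normalize_tracks(depth_tracks(sim$progenitor_alignments, lens,
                                        window = 10000))
    calls <- assign_subgenomes(tr)
    sub <- setNames(truth$haplotype_of$subgenome,
                    truth$haplotype_of$seq_id)
    expect_call <- ifelse(sub[calls$target_id] == "B", "brizantha",
                          "decumbens2x+ruziziensis")
    expect_equal(calls$assigned_source, unname(expect_call))
    ## switch detection on grouped tracks flags exactly the two events
    ct <- combine_tracks(tr, list(
      brizantha = "brizantha",
      decumbens = c("ruziziensis", "decumbens2x")))
    segs <- detect_switches(ct, min_segment = 10)
    expect_setequal(flagged_targets(segs),
                    unique(truth$event_intervals$target_id))
  }
})
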