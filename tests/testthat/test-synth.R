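test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(allelic_mislink_rate = 1.5), "rate")
  expect_error(sim_config(n_hic_pairs = 0), "positive")
  expect_error(sim_config(subgenome_divergence = 0.01,
                          haplotype_heterozygosity = 0.05), "exceed")
  expect_error(sim_config(planted_translocation = TRUE,
                          n_chromosomes_per_haplotype = 1), "2 base")
  expect_error(sim_config(exchange_start_frac = 0.7,
                          exchange_end_frac = 0.3), "bounds")
})

test_that("zero divergence and heterozygosity give identical haplotypes", {
  cfg <- sim_config(seed = 3, chromosome_length = 20000,
                    subgenome_divergence = 0,
                    haplotype_heterozygosity = 0,
                    n_repeat_families = 0, chr_family_copies = 0,
                    n_markers = 10, planted_exchange = FALSE,
                    planted_translocation = FALSE)
  g <- simulate_genome(cfg)
  chr1 <- as.character(g$genome[startsWith(names(g$genome), "chr1")])
  expect_equal(length(unique(unname(chr1))), 1L)
})

test_that("the genome is byte-identical across runs at the same seed", {
  cfg <- sim_config(seed = 11, chromosome_length = 30000, n_markers = 20,
                    n_hic_pairs = 500)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  g3 <- simulate_genome(sim_config(seed = 12, chromosome_length = 30000,
                                   n_markers = 20, n_hic_pairs = 500))
  expect_false(identical(as.character(g1$genome),
                         as.character(g3$genome)))
})

test_that("subgenome backbone divergence matches the configured rate", {
  sim <- cached_sim(1, events = TRUE)
  truth <- sim$truth
  cfg <- sim$config
  ## Hamming distance between the h1 backbones of base chromosome 1,
  ## restricted to single-copy (non-repeat, non-event) positions
  a <- strsplit(as.character(sim$genome[["chr1_A_h1"]]), "")[[1]]
  b <- strsplit(as.character(sim$genome[["chr1_B_h1"]]), "")[[1]]
  mask <- rep(TRUE, length(a))
  riv <- truth$repeat_intervals
  for (id in c("chr1_A_h1", "chr1_B_h1")) {
    rr <- riv[riv$target_id == id, ]
    for (i in seq_len(nrow(rr))) mask[(rr$start[i] + 1):rr$end[i]] <- FALSE
  }
  ev <- truth$event_intervals
  ex <- ev[ev$type == "homoeologous_exchange", ]
  mask[(ex$start + 1):ex$end] <- FALSE
  observed <- mean(a[mask] != b[mask])
  expect_lt(abs(observed - cfg$subgenome_divergence), 0.01)
})

test_that("unitig origin intervals tile each chromosome", {
  sim <- cached_sim(1, events = TRUE)
  u <- sim$truth$unitigs
  for (id in names(sim$genome)) {
    ui <- u[u$seq_id == id, ]
    ui <- ui[order(ui$start), ]
    expect_equal(ui$start[1], 0L)
    expect_equal(ui$end[nrow(ui)],
                 Biostrings::width(sim$genome[id]))
    expect_equal(ui$start[-1], ui$end[-nrow(ui)])
    expect_true(all(ui$end - ui$start >= sim$config$min_unitig))
  }
  ## unitig sequences equal the corresponding chromosome substrings
  i <- which(u$seq_id == "chr1_A_h1")[1]
  expect_equal(as.character(sim$unitigs[[u$unitig_id[i]]]),
               substr(as.character(sim$genome[["chr1_A_h1"]]),
                      u$start[i] + 1, u$end[i]))
})

test_that("no cut happens when the mean unitig exceeds the length", {
  cfg <- sim_config(seed = 2, chromosome_length = 10000, n_markers = 8,
                    planted_exchange = FALSE,
                    planted_translocation = FALSE)
  g <- simulate_genome(cfg)
  f <- fragment_unitigs(g$genome, g$truth, mean_unitig = 50000)
  expect_equal(nrow(f$truth$unitigs), length(g$genome))
})

test_that("marker hits: one per haplotype copy, table matches truth", {
  sim <- cached_sim(1, events = TRUE)
  expect_equal(nrow(sim$marker_hits), 4L * sim$config$n_markers)
  cnt <- table(sim$marker_hits$marker_id)
  expect_true(all(cnt == 4L))
  tab <- build_allelic_table(best_hit_per_marker_unitig(sim$marker_hits))
  expect_equal(tab$allelic_pairs, sim$truth$allelic_truth)

  ## full dropout leaves nothing
  mh <- simulate_marker_hits(sim$truth, dropout = 1)
  expect_equal(nrow(mh$hits), 0L)
})

test_that("hi-c pair counts and mislink fraction follow the config", {
  sim <- cached_sim(1, events = TRUE)
  cfg <- sim$config
  expect_equal(nrow(sim$hic_pairs), cfg$n_hic_pairs)
  cls <- sim$truth$pair_class
  expect_equal(length(cls), cfg$n_hic_pairs)
  rate <- mean(cls == "allelic_mislink")
  p <- cfg$allelic_mislink_rate
  expect_lt(abs(rate - p),
            3 * sqrt(p * (1 - p) / cfg$n_hic_pairs))
  ## zero rate produces zero mislinks
  cfg0 <- sim_config(seed = 4, chromosome_length = 50000, n_markers = 20,
                     n_hic_pairs = 300, allelic_mislink_rate = 0)
  s0 <- simulate_allotetraploid(cfg0)
  expect_equal(sum(s0$truth$pair_class == "allelic_mislink"), 0L)
})

test_that("cis pairs land within one chromosome; mislinks join sisters", {
  sim <- cached_sim(1, events = TRUE)
  truth <- sim$truth
  host <- setNames(truth$unitigs$seq_id, truth$unitigs$unitig_id)
  cls <- truth$pair_class[sim$hic_pairs$read_id]
  cis <- sim$hic_pairs[cls == "cis", ]
  expect_true(all(host[cis$uid1] == host[cis$uid2]))
  expect_true(all(cis$uid1 != cis$uid2))
  mis <- sim$hic_pairs[cls == "allelic_mislink", ]
  expect_true(all(host[mis$uid1] != host[mis$uid2]))
})

test_that("progenitor depth and event ancestry follow the truth set", {
  sim <- cached_sim(1, events = TRUE)
  truth <- sim$truth
  cfg <- sim$config
  lens <- setNames(truth$haplotype_of$length, truth$haplotype_of$seq_id)
  tr <- depth_tracks(sim$progenitor_alignments, lens, window = 10000)
  ## on-target mean depth within 10% of configured
  briz <- tr[tr$source == "brizantha" &
               tr$target_id == "chr1_B_h2", ]
  expect_lt(abs(mean(briz$depth) - cfg$progenitor_depth),
            0.1 * cfg$progenitor_depth)
  ## planted exchange interval is dominated by the donor subgenome
  ruz <- tr[tr$source == "ruziziensis" & tr$target_id == "chr1_B_h1", ]
  bz <- tr[tr$source == "brizantha" & tr$target_id == "chr1_B_h1", ]
  ev <- truth$event_intervals
  ex <- ev[ev$type == "homoeologous_exchange", ]
  inside <- ruz$start >= ex$start & ruz$end <= ex$end
  expect_true(all(ruz$depth[inside] > bz$depth[inside]))

  ## zero off-target ratio leaves other-subgenome chromosomes empty
  cfg0 <- sim_config(seed = 6, chromosome_length = 50000, n_markers = 20,
                     n_hic_pairs = 300, offtarget_depth_ratio = 0,
                     planted_exchange = FALSE,
                     planted_translocation = FALSE)
  g0 <- simulate_genome(cfg0)
  pa0 <- simulate_progenitor_alignments(g0$truth, cfg0)
  expect_equal(sum(pa0$brizantha$target_id %in%
                     grep("_A_", names(g0$genome), value = TRUE)), 0L)
})

test_that("planted events are recorded consistently with the sequences", {
  sim <- cached_sim(1, events = TRUE)
  truth <- sim$truth
  ev <- truth$event_intervals
  expect_setequal(ev$type, c("homoeologous_exchange", "translocation"))
  L <- sim$config$chromosome_length
  ## receiver grew, donor shrank by the translocated length
  t_len <- ev$end[ev$type == "translocation"] -
    ev$start[ev$type == "translocation"]
  expect_equal(unname(Biostrings::width(sim$genome["chr2_A_h1"])),
               L + t_len)
  expect_equal(unname(Biostrings::width(sim$genome["chr2_B_h1"])),
               L - t_len)
  ## translocated tail equals the donor's former start
  ## (both carried B-subgenome sequence before the move)
  tail_seq <- substr(as.character(sim$genome[["chr2_A_h1"]]), L + 1,
                     L + t_len)
  h2_start <- substr(as.character(sim$genome[["chr2_B_h2"]]), 1, t_len)
  expect_gt(mean(strsplit(tail_seq, "")[[1]] ==
                   strsplit(h2_start, "")[[1]]), 0.95)
  ## exchange interval matches the A donor exactly
  ex <- ev[ev$type == "homoeologous_exchange", ]
  got <- substr(as.character(sim$genome[["chr1_B_h1"]]), ex$start + 1,
                ex$end)
  donor <- substr(as.character(sim$genome[["chr1_A_h1"]]), ex$start + 1,
                  ex$end)
  expect_identical(got, donor)
})
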