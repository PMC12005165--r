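## Synthetic allotetraploid generator.
##
## Emulates the data structure of a phased tetraploid assembly project:
## two subgenomes (A, B) derived from a common ancestor at
## `subgenome_divergence`, two haplotypes per subgenome separated by
## `haplotype_heterozygosity`, a dispersed repeat component whose family
## abundances are subgenome-specific (the signal that lets abundance-
## weighted k-mer signatures separate subgenomes while presence/absence
## signatures pair homologous chromosomes), single-copy marker loci hit
## once per haplotype, Hi-C pairs with a power-law contact decay plus an
## allelic mis-mapping fraction anchored at marker loci, progenitor read
## alignments with on/off-target depth, and one planted homoeologous
## exchange and one planted terminal translocation. Every generator is
## deterministic under the configured seed, and a truth set records
## everything needed to score each pipeline stage.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic
#' allotetraploid generator. Defaults define the standard study
#' scenario used throughout the test-suite.
#'
#' @param n_chromosomes_per_haplotype base chromosomes per haplotype.
#' @param chromosome_length length of each base chromosome (bp).
#' @param subgenome_divergence substitution rate between subgenomes.
#' @param haplotype_heterozygosity substitution rate between the two
#'   haplotypes of a subgenome.
#' @param n_markers number of single-copy marker loci.
#' @param n_hic_pairs number of Hi-C pairs to simulate.
#' @param allelic_mislink_rate fraction of Hi-C pairs mis-mapped between
#'   sister haplotypes at a homologous locus.
#' @param contact_decay_exponent power-law exponent of the cis contact
#'   distance decay.
#' @param progenitor_depth mean on-target read depth per progenitor.
#' @param offtarget_depth_ratio off-target/on-target depth ratio.
#' @param planted_exchange plant a homoeologous exchange (an internal
#'   interval of one B-subgenome chromosome replaced by the homoeologous
#'   A interval)?
#' @param planted_translocation plant a terminal translocation (the
#'   start of one B chromosome moved to the end of an A chromosome)?
#' @param seed master RNG seed; each generator stage derives its own
#'   sub-seed from it.
#' @param n_repeat_families number of shared dispersed repeat families.
#' @param repeat_length repeat unit length (bp).
#' @param repeat_copies_high,repeat_copies_low per-chromosome copy
#'   numbers of a family in the subgenome where it is amplified vs not.
#' @param chr_family_copies per-chromosome copies of each chromosome-
#'   specific repeat family (shared across subgenomes).
#' @param exchange_start_frac,exchange_end_frac planted-exchange interval
#'   as fractions of chromosome length.
#' @param translocation_frac fraction of the donor chromosome moved by
#'   the planted translocation.
#' @param mean_unitig,min_unitig mean and minimum unitig length for
#'   fragmentation (bp).
#' @param min_separation minimum cis Hi-C pair separation (bp).
#' @param mislink_mapq_high_frac fraction of mis-mapped pairs that keep
#'   MAPQ 60 (the rest draw MAPQ uniformly in 0-29).
#' @param trans_background_rate fraction of pairs drawn as random
#'   cross-chromosome noise contacts.
#' @param marker_dropout per-hit dropout probability for marker hits.
#' @param read_length progenitor read length (bp).
#' @param sources named character vector mapping progenitor source name
#'   to the subgenome it matches.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes_per_haplotype = 2L,
                       chromosome_length = 500000L,
                       subgenome_divergence = 0.10,
                       haplotype_heterozygosity = 0.01,
                       n_markers = 200L,
                       n_hic_pairs = 50000L,
                       allelic_mislink_rate = 0.10,
                       contact_decay_exponent = 1.0,
                       progenitor_depth = 20,
                       offtarget_depth_ratio = 0.1,
                       planted_exchange = TRUE,
                       planted_translocation = TRUE,
                       seed = 1L,
                       n_repeat_families = 16L,
                       repeat_length = 400L,
                       repeat_copies_high = 10L,
                       repeat_copies_low = 2L,
                       chr_family_copies = 6L,
                       exchange_start_frac = 0.35,
                       exchange_end_frac = 0.65,
                       translocation_frac = 0.20,
                       mean_unitig = 25000L,
                       min_unitig = 5000L,
                       min_separation = 1000L,
                       mislink_mapq_high_frac = 0.6,
                       trans_background_rate = 0,
                       marker_dropout = 0,
                       read_length = 1000L,
                       sources = c(brizantha = "B", ruziziensis = "A",
                                   decumbens2x = "A")) {
  cfg <- list(n_chromosomes_per_haplotype =
                as.integer(n_chromosomes_per_haplotype),
              chromosome_length = as.integer(chromosome_length),
              subgenome_divergence = subgenome_divergence,
              haplotype_heterozygosity = haplotype_heterozygosity,
              n_markers = as.integer(n_markers),
              n_hic_pairs = as.integer(n_hic_pairs),
              allelic_mislink_rate = allelic_mislink_rate,
              contact_decay_exponent = contact_decay_exponent,
              progenitor_depth = progenitor_depth,
              offtarget_depth_ratio = offtarget_depth_ratio,
              planted_exchange = isTRUE(planted_exchange),
              planted_translocation = isTRUE(planted_translocation),
              seed = as.integer(seed),
              n_repeat_families = as.integer(n_repeat_families),
              repeat_length = as.integer(repeat_length),
              repeat_copies_high = as.integer(repeat_copies_high),
              repeat_copies_low = as.integer(repeat_copies_low),
              chr_family_copies = as.integer(chr_family_copies),
              exchange_start_frac = exchange_start_frac,
              exchange_end_frac = exchange_end_frac,
              translocation_frac = translocation_frac,
              mean_unitig = as.integer(mean_unitig),
              min_unitig = as.integer(min_unitig),
              min_separation = as.integer(min_separation),
              mislink_mapq_high_frac = mislink_mapq_high_frac,
              trans_background_rate = trans_background_rate,
              marker_dropout = marker_dropout,
              read_length = as.integer(read_length),
              sources = sources)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rate_fields <- c("subgenome_divergence", "haplotype_heterozygosity",
                   "allelic_mislink_rate", "offtarget_depth_ratio",
                   "mislink_mapq_high_frac", "trans_background_rate",
                   "marker_dropout")
  for (f in rate_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("config field '", f, "' must be a rate in [0, 1]", call. = FALSE)
    }
  }
  pos_fields <- c("n_chromosomes_per_haplotype", "chromosome_length",
                  "n_markers", "n_hic_pairs", "progenitor_depth",
                  "mean_unitig", "min_unitig", "min_separation",
                  "read_length", "repeat_length")
  for (f in pos_fields) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be positive", call. = FALSE)
    }
  }
  if (cfg$subgenome_divergence > 0 &&
      cfg$subgenome_divergence <= cfg$haplotype_heterozygosity) {
    stop("subgenome_divergence must exceed haplotype_heterozygosity",
         call. = FALSE)
  }
  if (cfg$planted_translocation && cfg$n_chromosomes_per_haplotype < 2L) {
    stop("planted translocation needs >= 2 base chromosomes",
         call. = FALSE)
  }
  if (cfg$exchange_start_frac >= cfg$exchange_end_frac ||
      cfg$exchange_start_frac < 0 || cfg$exchange_end_frac > 1) {
    stop("exchange interval fractions out of bounds", call. = FALSE)
  }
  if (is.null(names(cfg$sources)) || !all(cfg$sources %in% c("A", "B"))) {
    stop("sources must be a named vector of subgenome labels A/B",
         call. = FALSE)
  }
  invisible(cfg)
}

seq_name <- function(basechr, sub, hap) {
  sprintf("chr%d_%s_h%d", basechr, sub, hap)
}

## per-base substitution at `rate`; replacement drawn uniformly from the
## other three bases, so every selected site changes
mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  i <- which(runif(length(x)) < rate)
  if (length(i) > 0L) {
    x[i] <- ((x[i] - 1L + sample.int(3L, length(i), replace = TRUE)) %% 4L) + 1L
  }
  x
}

#' Simulate the allotetraploid genome
#'
#' Draws an ancestor per base chromosome, derives subgenome B by per-base
#' substitution at `subgenome_divergence`, derives haplotype 2 of each
#' subgenome at `haplotype_heterozygosity` (haplotype 1 is the subgenome
#' backbone), plants the dispersed-repeat component, and applies the
#' configured rearrangement events. Sequence ids follow the pattern
#' `chr<base>_<subgenome>_h<haplotype>`, e.g. `chr1_A_h1`.
#'
#' @param config a `sim_config`.
#' @return list with `genome` (a `DNAStringSet`) and `truth` (truth set:
#'   `haplotype_of`, `ancestry_intervals`, `event_intervals`,
#'   `repeat_intervals`, `marker_loci`, `config`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 1L))
  L <- config$chromosome_length
  nchr <- config$n_chromosomes_per_haplotype
  subs <- c("A", "B")

  ancestors <- lapply(seq_len(nchr),
                      function(i) sample.int(4L, L, replace = TRUE))

  ## repeat library: shared families (half amplified in A, half in B)
  ## plus one low-copy family per base chromosome shared by all copies
  nf <- config$n_repeat_families
  rl <- config$repeat_length
  fam_seq <- lapply(seq_len(nf),
                    function(i) sample.int(4L, rl, replace = TRUE))
  chrfam_seq <- lapply(seq_len(nchr),
                       function(i) sample.int(4L, rl, replace = TRUE))
  fam_high_in_A <- if (nf > 0L) seq_len(nf) <= nf %/% 2L else logical()

  seqs <- list()
  rep_iv <- list()
  for (b in seq_len(nchr)) {
    backbone <- list(A = ancestors[[b]],
                     B = mutate_seq(ancestors[[b]],
                                    config$subgenome_divergence))
    for (s in subs) {
      h1 <- backbone[[s]]
      h2 <- mutate_seq(backbone[[s]], config$haplotype_heterozygosity)
      ## repeat placement: per (base chromosome, subgenome), identical in
      ## both haplotypes; copies are exact so repeat k-mers are shared
      ## genome-wide and only their abundances carry subgenome identity
      starts <- integer()
      fams <- integer()
      if (nf > 0L) {
        for (f in seq_len(nf)) {
          copies <- if (xor(s == "A", !fam_high_in_A[f])) {
            config$repeat_copies_high
          } else {
            config$repeat_copies_low
          }
          if (copies > 0L) {
            st <- sample.int(L - rl, copies, replace = TRUE)
            starts <- c(starts, st)
            fams <- c(fams, rep(f, copies))
          }
        }
      }
      cf <- config$chr_family_copies
      if (cf > 0L) {
        st <- sample.int(L - rl, cf, replace = TRUE)
        starts <- c(starts, st)
        fams <- c(fams, rep(0L, cf))  # 0 marks the chromosome family
      }
      for (j in seq_along(starts)) {
        txt <- if (fams[j] == 0L) chrfam_seq[[b]] else fam_seq[[fams[j]]]
        idx <- starts[j]:(starts[j] + rl - 1L)
        h1[idx] <- txt
        h2[idx] <- txt
      }
      seqs[[seq_name(b, s, 1L)]] <- h1
      seqs[[seq_name(b, s, 2L)]] <- h2
      if (length(starts) > 0L) {
        for (h in 1:2) {
          rep_iv[[length(rep_iv) + 1L]] <-
            data.frame(target_id = seq_name(b, s, h),
                       start = starts - 1L, end = starts - 1L + rl,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }

  ## ancestry defaults: each sequence carries its own subgenome
  ids <- names(seqs)
  meta <- do.call(rbind, lapply(ids, function(id) {
    p <- strsplit(id, "_", fixed = TRUE)[[1L]]
    data.frame(seq_id = id,
               base_chromosome = as.integer(sub("chr", "", p[1L])),
               subgenome = p[2L],
               haplotype = as.integer(sub("h", "", p[3L])),
               stringsAsFactors = FALSE)
  }))
  anc_iv <- data.frame(seq_id = meta$seq_id, start = 0L, end = L,
                       subgenome = meta$subgenome,
                       stringsAsFactors = FALSE)
  events <- data.frame(type = character(), target_id = character(),
                       start = integer(), end = integer(),
                       source_subgenome = character(),
                       stringsAsFactors = FALSE)
  translocation <- NULL

  if (config$planted_exchange) {
    es <- as.integer(round(config$exchange_start_frac * L))
    ee <- as.integer(round(config$exchange_end_frac * L))
    tgt <- seq_name(1L, "B", 1L)
    donor <- seq_name(1L, "A", 1L)
    seqs[[tgt]][(es + 1L):ee] <- seqs[[donor]][(es + 1L):ee]
    events <- rbind(events,
                    data.frame(type = "homoeologous_exchange",
                               target_id = tgt, start = es, end = ee,
                               source_subgenome = "A",
                               stringsAsFactors = FALSE))
    anc_iv <- anc_iv[anc_iv$seq_id != tgt, , drop = FALSE]
    anc_iv <- rbind(anc_iv,
                    data.frame(seq_id = tgt, start = c(0L, es, ee),
                               end = c(es, ee, L),
                               subgenome = c("B", "A", "B"),
                               stringsAsFactors = FALSE))
  }

  if (config$planted_translocation) {
    t_len <- as.integer(round(config$translocation_frac * L))
    donor <- seq_name(2L, "B", 1L)
    recv <- seq_name(2L, "A", 1L)
    seg <- seqs[[donor]][1:t_len]
    seqs[[recv]] <- c(seqs[[recv]], seg)
    seqs[[donor]] <- seqs[[donor]][(t_len + 1L):L]
    translocation <- list(donor = donor, receiver = recv, t_len = t_len,
                          base_chromosome = 2L, orig_length = L)
    events <- rbind(events,
                    data.frame(type = "translocation", target_id = recv,
                               start = L, end = L + t_len,
                               source_subgenome = "B",
                               stringsAsFactors = FALSE))
    anc_iv <- anc_iv[!anc_iv$seq_id %in% c(donor, recv), , drop = FALSE]
    anc_iv <- rbind(anc_iv,
                    data.frame(seq_id = c(recv, recv, donor),
                               start = c(0L, L, 0L),
                               end = c(L, L + t_len, L - t_len),
                               subgenome = c("A", "B", "B"),
                               stringsAsFactors = FALSE))
    ## repeat intervals move with the sequence edits
    riv <- do.call(rbind, rep_iv)
    don <- riv$target_id == donor
    riv$start[don] <- riv$start[don] - t_len
    riv$end[don] <- riv$end[don] - t_len
    keep <- !(don & riv$start < 0L)
    rep_iv <- list(riv[keep, , drop = FALSE])
  }

  meta$length <- vapply(seqs[meta$seq_id], length, 0L)

  ## marker loci: uniform over each base chromosome's ancestor coordinates
  per_chr <- diff(round(seq(0, config$n_markers, length.out = nchr + 1L)))
  loci <- do.call(rbind, lapply(seq_len(nchr), function(b) {
    pos <- sort(sample.int(L - 2000L, per_chr[b]) + 1000L)
    data.frame(base_chromosome = b, pos = pos, stringsAsFactors = FALSE)
  }))
  loci$marker_id <- sprintf("marker%04d", seq_len(nrow(loci)))
  loci <- loci[, c("marker_id", "base_chromosome", "pos")]

  genome <- Biostrings::DNAStringSet(
    vapply(seqs, function(x) paste(BASES[x], collapse = ""), ""))
  names(genome) <- names(seqs)

  repeat_intervals <- do.call(rbind, rep_iv)
  rownames(repeat_intervals) <- NULL
  truth <- list(haplotype_of = meta,
                ancestry_intervals =
                  anc_iv[order(anc_iv$seq_id, anc_iv$start), ],
                event_intervals = events,
                repeat_intervals = repeat_intervals,
                marker_loci = loci,
                translocation = translocation,
                config = config)
  list(genome = genome, truth = truth)
}

## 0-based half-open unitig intervals per sequence, derived from uniform
## random breakpoints; fragments shorter than min_unitig are merged into
## a neighbour (assemblers do not emit tiny unitigs, and zero-contact
## fragments would only add noise downstream)
#' Fragment chromosomes into unitigs
#'
#' Cuts each haplotype chromosome at uniform random breakpoints into
#' unitigs with the requested mean length; fragments below `min_unitig`
#' are merged into a neighbour. The truth set records each unitig's
#' origin interval.
#'
#' @param genome a `DNAStringSet` from [simulate_genome()].
#' @param truth the accompanying truth set.
#' @param mean_unitig target mean unitig length (bp); defaults to the
#'   config value.
#' @param min_unitig minimum unitig length (bp).
#' @return list with `unitigs` (a `DNAStringSet`) and `truth` (with a
#'   `unitigs` data.frame `unitig_id`, `seq_id`, `start`, `end`).
#' @export
fragment_unitigs <- function(genome, truth, mean_unitig = NULL,
                             min_unitig = NULL) {
  cfg <- truth$config
  if (is.null(mean_unitig)) mean_unitig <- cfg$mean_unitig
  if (is.null(min_unitig)) min_unitig <- cfg$min_unitig
  set.seed(stage_seed(cfg$seed, 2L))
  tabs <- lapply(names(genome), function(id) {
    len <- Biostrings::width(genome[id])
    n_cuts <- max(0L, as.integer(round(len / mean_unitig)) - 1L)
    bp <- if (n_cuts > 0L) sort(sample.int(len - 1L, min(n_cuts, len - 1L)))
          else integer()
    bounds <- c(0L, bp, len)
    w <- diff(bounds)
    ## merge undersized fragments into the left neighbour (right for the
    ## first fragment) until all fragments reach min_unitig
    while (length(w) > 1L && any(w < min_unitig)) {
      i <- which.min(w)
      j <- if (i == 1L) 2L else i - 1L
      w[j] <- w[j] + w[i]
      w <- w[-i]
    }
    ends <- cumsum(w)
    starts <- c(0L, ends[-length(ends)])
    data.frame(seq_id = id, start = as.integer(starts),
               end = as.integer(ends), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  tab$unitig_id <- sprintf("utg%05d", seq_len(nrow(tab)))
  tab <- tab[, c("unitig_id", "seq_id", "start", "end")]
  rownames(tab) <- NULL
  useqs <- Biostrings::DNAStringSet(substring(
    as.character(genome[tab$seq_id]), tab$start + 1L, tab$end))
  names(useqs) <- tab$unitig_id
  truth$unitigs <- tab
  list(unitigs = useqs, truth = truth)
}

## unitig containing 0-based position `pos` on sequence `seq_id`
unitig_at <- function(truth, seq_id, pos) {
  u <- truth$unitigs[truth$unitigs$seq_id == seq_id, , drop = FALSE]
  i <- findInterval(pos, u$start)
  list(unitig_id = u$unitig_id[i], upos = pos - u$start[i])
}

## table of every marker locus copy: position and unitig per haplotype
## copy, with the planted translocation's coordinate moves applied
marker_copy_table <- function(truth) {
  cfg <- truth$config
  loci <- truth$marker_loci
  tr <- truth$translocation
  rows <- list()
  for (s in c("A", "B")) {
    for (h in 1:2) {
      seq_id <- seq_name(loci$base_chromosome, s, h)
      pos <- loci$pos
      if (!is.null(tr) && s == "B" && h == 1L) {
        on_donor <- seq_name(loci$base_chromosome, "B", 1L) == tr$donor
        moved <- on_donor & pos < tr$t_len
        shifted <- on_donor & pos >= tr$t_len
        seq_id[moved] <- tr$receiver
        pos[moved] <- tr$orig_length + pos[moved]
        pos[shifted] <- pos[shifted] - tr$t_len
      }
      rows[[paste(s, h)]] <-
        data.frame(marker_id = loci$marker_id, subgenome = s,
                   haplotype = h, seq_id = seq_id, pos = pos,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ## attach unitigs
  tab$unitig_id <- NA_character_
  tab$upos <- NA_integer_
  for (id in unique(tab$seq_id)) {
    sel <- tab$seq_id == id
    u <- unitig_at(truth, id, tab$pos[sel])
    tab$unitig_id[sel] <- u$unitig_id
    tab$upos[sel] <- u$upos
  }
  tab
}

#' Simulate single-copy marker hits
#'
#' Each marker locus yields one protein hit per haplotype copy (four in
#' total) onto the unitig containing the locus, minus dropout. Percent
#' identity reflects the copy's substitution distance from the ancestor
#' consensus, so bitscores decrease with divergence.
#'
#' @param truth truth set after [fragment_unitigs()].
#' @param dropout per-hit dropout probability.
#' @return list with `hits` (marker-hit data.frame) and `truth`
#'   (augmented with `allelic_truth`, the marker-induced unitig pairs).
#' @export
simulate_marker_hits <- function(truth, dropout = NULL) {
  cfg <- truth$config
  if (is.null(dropout)) dropout <- cfg$marker_dropout
  set.seed(stage_seed(cfg$seed, 3L))
  mc <- marker_copy_table(truth)
  div <- cfg$subgenome_divergence
  het <- cfg$haplotype_heterozygosity
  identity <- 100 * (1 - ifelse(mc$subgenome == "B", div, 0) -
                       ifelse(mc$haplotype == 2L, het, 0))
  bitscore <- round(6 * identity, 1)
  hits <- data.frame(marker_id = mc$marker_id, unitig_id = mc$unitig_id,
                     percent_identity = round(identity, 2),
                     bitscore = bitscore,
                     evalue = signif(10^(-bitscore / 10), 3),
                     stringsAsFactors = FALSE)
  ## marker-induced homologous unitig pairs are the pruning truth
  pairs <- do.call(rbind, lapply(split(mc$unitig_id, mc$marker_id),
                                 function(u) {
    u <- sort(unique(u))
    if (length(u) < 2L) return(NULL)
    cb <- utils::combn(u, 2L)
    data.frame(u1 = cb[1L, ], u2 = cb[2L, ], stringsAsFactors = FALSE)
  }))
  pairs <- pairs[!duplicated(paste(pairs$u1, pairs$u2, sep = "\t")), ,
                 drop = FALSE]
  pairs <- pairs[order(pairs$u1, pairs$u2), , drop = FALSE]
  rownames(pairs) <- NULL
  truth$allelic_truth <- pairs
  truth$marker_copies <- mc
  if (dropout > 0) {
    hits <- hits[runif(nrow(hits)) >= dropout, , drop = FALSE]
    rownames(hits) <- NULL
  }
  list(hits = hits, truth = truth)
}

## power-law separation: inverse-CDF sample of P(s) ~ s^-alpha on
## [smin, smax]
draw_separation <- function(n, alpha, smin, smax) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-9) {
    s <- smin * (smax / smin)^u
  } else {
    a <- 1 - alpha
    s <- (smin^a + u * (smax^a - smin^a))^(1 / a)
  }
  pmin(pmax(round(s), smin), smax)
}

#' Simulate Hi-C pairs
#'
#' Each pair is, with probability `1 - allelic_mislink_rate -
#' trans_background_rate`, a cis contact on one haplotype chromosome with
#' power-law separation; with probability `allelic_mislink_rate` an
#' allelic mis-mapped contact joining the two sister haplotypes of one
#' subgenome at a single-copy marker locus (mis-mapping concentrates
#' where haplotypes are locally near-identical, which is exactly where
#' the single-copy markers sit, so every mis-link joins marker-covered
#' allelic unitigs); with probability `trans_background_rate` a uniform
#' random cross-chromosome noise contact. Cis pairs are redrawn until
#' they join two different unitigs (intra-unitig contacts carry no
#' scaffolding information). MAPQ is 60 for cis pairs and a
#' high/low mixture for mis-links; all flags are 0.
#'
#' @param truth truth set after [simulate_marker_hits()].
#' @param config a `sim_config` (defaults to the one in `truth`).
#' @return list with `pairs` (contact-pair data.frame), `truth`
#'   (augmented with `pair_class`, a vector keyed by read id with values
#'   `cis`, `allelic_mislink` or `trans_background`).
#' @export
simulate_hic_pairs <- function(truth, config = NULL) {
  if (is.null(config)) config <- truth$config
  set.seed(stage_seed(config$seed, 4L))
  n <- config$n_hic_pairs
  u <- runif(n)
  cls <- ifelse(u < config$allelic_mislink_rate, "allelic_mislink",
                ifelse(u < config$allelic_mislink_rate +
                         config$trans_background_rate,
                       "trans_background", "cis"))
  meta <- truth$haplotype_of
  lens <- setNames(meta$length, meta$seq_id)
  utab <- truth$unitigs

  uid1 <- character(n); pos1 <- integer(n)
  uid2 <- character(n); pos2 <- integer(n)
  mapq1 <- rep(60L, n); mapq2 <- rep(60L, n)

  lookup <- function(seq_id, pos) {
    out_id <- character(length(seq_id)); out_p <- integer(length(seq_id))
    for (id in unique(seq_id)) {
      sel <- seq_id == id
      r <- unitig_at(truth, id, pos[sel])
      out_id[sel] <- r$unitig_id
      out_p[sel] <- r$upos
    }
    list(unitig_id = out_id, upos = out_p)
  }

  ## cis contacts (redraw until inter-unitig)
  ci <- which(cls == "cis")
  todo <- ci
  while (length(todo) > 0L) {
    m <- length(todo)
    seq_id <- sample(meta$seq_id, m, replace = TRUE, prob = meta$length)
    Lc <- lens[seq_id]
    smax <- Lc - 1
    s <- draw_separation(m, config$contact_decay_exponent,
                         config$min_separation, smax)
    p1 <- floor(runif(m) * (Lc - s))
    p2 <- p1 + s
    r1 <- lookup(seq_id, p1)
    r2 <- lookup(seq_id, p2)
    ok <- r1$unitig_id != r2$unitig_id
    idx <- todo[ok]
    uid1[idx] <- r1$unitig_id[ok]; pos1[idx] <- r1$upos[ok]
    uid2[idx] <- r2$unitig_id[ok]; pos2[idx] <- r2$upos[ok]
    todo <- todo[!ok]
  }

  ## allelic mis-links anchored at marker loci
  mi <- which(cls == "allelic_mislink")
  if (length(mi) > 0L) {
    mc <- truth$marker_copies
    m <- length(mi)
    midx <- sample(nrow(truth$marker_loci), m, replace = TRUE)
    mid <- truth$marker_loci$marker_id[midx]
    sub <- sample(c("A", "B"), m, replace = TRUE)
    k1 <- match(paste(mid, sub, 1L), paste(mc$marker_id, mc$subgenome,
                                           mc$haplotype))
    k2 <- match(paste(mid, sub, 2L), paste(mc$marker_id, mc$subgenome,
                                           mc$haplotype))
    uid1[mi] <- mc$unitig_id[k1]; pos1[mi] <- mc$upos[k1]
    uid2[mi] <- mc$unitig_id[k2]; pos2[mi] <- mc$upos[k2]
    low <- runif(m) >= config$mislink_mapq_high_frac
    mapq2[mi[low]] <- sample(0:29, sum(low), replace = TRUE)
  }

  ## random cross-chromosome background
  ti <- which(cls == "trans_background")
  if (length(ti) > 0L) {
    m <- length(ti)
    s1 <- sample(meta$seq_id, m, replace = TRUE, prob = meta$length)
    s2 <- sample(meta$seq_id, m, replace = TRUE, prob = meta$length)
    p1 <- floor(runif(m) * lens[s1])
    p2 <- floor(runif(m) * lens[s2])
    r1 <- lookup(s1, p1); r2 <- lookup(s2, p2)
    uid1[ti] <- r1$unitig_id; pos1[ti] <- r1$upos
    uid2[ti] <- r2$unitig_id; pos2[ti] <- r2$upos
  }

  read_id <- sprintf("hic%06d", seq_len(n))
  pairs <- data.frame(read_id = read_id, uid1 = uid1, pos1 = pos1,
                      mapq1 = mapq1, flags1 = 0L, uid2 = uid2,
                      pos2 = pos2, mapq2 = mapq2, flags2 = 0L,
                      stringsAsFactors = FALSE)
  truth$pair_class <- setNames(cls, read_id)
  list(pairs = pairs, truth = truth)
}

#' Simulate progenitor read alignments
#'
#' For each candidate progenitor source, read-length alignments are
#' placed on every ancestry interval at the on-target depth when the
#' interval's true subgenome matches the source and at
#' `progenitor_depth * offtarget_depth_ratio` otherwise; planted-event
#' intervals therefore follow their true donor ancestry. Read counts per
#' interval are Poisson around the expectation.
#'
#' @param truth truth set from [simulate_genome()] (or later).
#' @param config a `sim_config` (defaults to the one in `truth`).
#' @return named list of alignment data.frames, one per source.
#' @export
simulate_progenitor_alignments <- function(truth, config = NULL) {
  if (is.null(config)) config <- truth$config
  set.seed(stage_seed(config$seed, 5L))
  iv <- truth$ancestry_intervals
  rl <- config$read_length
  out <- lapply(names(config$sources), function(src) {
    sub <- config$sources[[src]]
    recs <- lapply(seq_len(nrow(iv)), function(i) {
      len <- iv$end[i] - iv$start[i]
      depth <- if (iv$subgenome[i] == sub) config$progenitor_depth
               else config$progenitor_depth * config$offtarget_depth_ratio
      this_rl <- min(rl, len)
      n_reads <- rpois(1L, depth * len / this_rl)
      if (n_reads == 0L) return(NULL)
      start <- iv$start[i] +
        floor(runif(n_reads) * (len - this_rl + 1L))
      data.frame(query_id = sprintf("%s_r%07d", src, seq_len(n_reads)),
                 target_id = iv$seq_id[i], target_start = as.integer(start),
                 target_end = as.integer(start + this_rl), mapq = 60L,
                 flags = 0L, stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    rownames(recs) <- NULL
    recs
  })
  names(out) <- names(config$sources)
  out
}

#' Run the full simulator
#'
#' Convenience wrapper chaining genome simulation, unitig fragmentation,
#' marker hits, Hi-C pairs and progenitor alignments under one config.
#'
#' @param config a `sim_config`.
#' @return list with `genome`, `unitigs`, `truth`, `marker_hits`,
#'   `hic_pairs`, `progenitor_alignments`, `config`.
#' @export
simulate_allotetraploid <- function(config = sim_config()) {
  g <- simulate_genome(config)
  f <- fragment_unitigs(g$genome, g$truth)
  mh <- simulate_marker_hits(f$truth)
  hp <- simulate_hic_pairs(mh$truth)
  pa <- simulate_progenitor_alignments(hp$truth)
  list(genome = g$genome, unitigs = f$unitigs, truth = hp$truth,
       marker_hits = mh$hits, hic_pairs = hp$pairs,
       progenitor_alignments = pa, config = config)
}
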