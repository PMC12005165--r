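## End-to-end pipeline driver on synthetic data: simulate, build the
## allelic table, prune the Hi-C stream, quantify the pruning effect on
## the contact matrix, assign subgenome ancestry and detect switches,
## cluster k-mer signatures under the strict-cut criterion, and emit
## curation tracks, all merged into one machine-readable report.

#' Run every pipeline stage on a synthetic allotetraploid
#'
#' Executes the stages in dependency order and returns the merged
#' per-stage report; optionally serializes it as JSON. The synthetic
#' truth set is used only to score results (grouping agreement, ancestry
#' accuracy), never inside the pipeline stages themselves.
#'
#' @param config a [run_config()]; its `sim` block parameterizes the
#'   simulator and its `seed` seeds every stage.
#' @param report_path optional path for the JSON run report.
#' @return invisibly, a list with the per-stage results (`allelic`,
#'   `prune`, `contact`, `ancestry`, `kmersig`, `tracks`) and `report`
#'   (the serializable summary).
#' @export
run_synthetic_pipeline <- function(config = run_config(),
                                   report_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
  scfg <- do.call(sim_config, sim_args)
  sim <- simulate_allotetraploid(scfg)
  truth <- sim$truth
  unitig_lengths <- setNames(truth$unitigs$end - truth$unitigs$start,
                             truth$unitigs$unitig_id)
  n_groups <- if (is.null(config$n_groups)) {
    nrow(truth$haplotype_of)
  } else {
    config$n_groups
  }

  ## allelic table from marker hits
  hits <- best_hit_per_marker_unitig(sim$marker_hits)
  table <- build_allelic_table(hits, ploidy = config$ploidy,
                               min_identity = config$min_identity)
  hist <- copy_number_histogram(table)

  ## Hi-C pruning
  pruned <- prune_pipeline(sim$hic_pairs, table, mask = config$mask,
                           min_mapq = config$min_mapq)

  ## contact matrices before/after and the pruning effect
  m_before <- build_contact_matrix(sim$hic_pairs, unitig_lengths)
  m_after <- build_contact_matrix(pruned$pairs, unitig_lengths)
  frac_before <- inter_allelic_fraction(m_before, table)
  frac_after <- inter_allelic_fraction(m_after, table)
  truth_groups <- setNames(truth$unitigs$seq_id, truth$unitigs$unitig_id)
  g_before <- group_unitigs(m_before, k = n_groups)
  g_after <- group_unitigs(m_after, k = n_groups)
  agree_before <- pair_agreement(truth_groups, g_before)
  agree_after <- pair_agreement(truth_groups, g_after)

  ## ancestry from progenitor alignments
  target_lengths <- setNames(truth$haplotype_of$length,
                             truth$haplotype_of$seq_id)
  tracks <- depth_tracks(sim$progenitor_alignments, target_lengths,
                         window = config$window)
  tracks <- normalize_tracks(tracks)
  calls <- assign_subgenomes(tracks, config$margin_threshold)
  src_groups <- source_groups(calls, scfg$sources)
  seg_tracks <- if (length(src_groups) < length(scfg$sources)) {
    combine_tracks(tracks, src_groups)
  } else {
    tracks
  }
  segments <- detect_switches(seg_tracks, config$min_segment)
  flagged <- flagged_targets(segments)

  ## k-mer signatures on the assembled chromosomes
  sub_labels <- setNames(truth$haplotype_of$subgenome,
                         truth$haplotype_of$seq_id)
  kres <- lapply(config$k_list, function(k) {
    sigs <- sketch_set(sim$genome, k = k, scaled = config$scaled)
    out <- lapply(c("composition", "frequency"), function(mode) {
      sm <- similarity_matrix(sigs, mode = mode)
      hc <- cluster_signatures(sm)
      sc <- strict_cut_check(hc, sub_labels,
                             n_subgenomes = length(unique(sub_labels)))
      list(mode = mode, pass = sc$pass, offenders = sc$offenders)
    })
    names(out) <- c("composition", "frequency")
    list(k = k, modes = out)
  })
  names(kres) <- paste0("k", config$k_list)

  ## curation tracks
  gaps <- find_gaps(sim$genome, min_run = config$min_run)
  telo <- telomere_density(sim$genome, motif = config$motif,
                           window = config$window)

  report <- list(
    allelic = list(n_markers = length(table$marker_to_unitigs),
                   n_allelic_pairs = nrow(table$allelic_pairs),
                   n_flagged = length(table$flagged_markers),
                   histogram_mode = hist$copies[which.max(hist$n_markers)]),
    prune = list(n_input = pruned$report$n_input,
                 n_flag_removed = pruned$report$n_flag_removed,
                 n_mapq_removed = pruned$report$n_mapq_removed,
                 n_allelic_removed = pruned$report$n_allelic_removed,
                 n_output = pruned$report$n_output),
    contact = list(inter_allelic_fraction_before = frac_before,
                   inter_allelic_fraction_after = frac_after,
                   grouping_agreement_before = agree_before,
                   grouping_agreement_after = agree_after),
    ancestry = list(calls = calls, n_flagged_targets = length(flagged),
                    flagged_targets = flagged),
    kmersig = lapply(kres, function(x) {
      list(k = x$k,
           composition_pass = x$modes$composition$pass,
           frequency_pass = x$modes$frequency$pass)
    }),
    tracks = list(n_gaps = nrow(gaps),
                  n_telomere_hits = sum(telo$count)),
    seed = config$seed)

  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(sim = sim, allelic = table, histogram = hist,
                 prune = pruned, contact = list(before = m_before,
                                                after = m_after),
                 ancestry = list(tracks = tracks, calls = calls,
                                 segments = segments, flagged = flagged),
                 kmersig = kres,
                 tracks = list(gaps = gaps, telomere = telo),
                 report = report))
}

## Derive source groups for switch detection from the genome-wide calls:
## sources that appear together in a combined "a+b" call are summed into
## one track; everything else stays single.
source_groups <- function(calls, sources) {
  labs <- unique(calls$assigned_source)
  labs <- labs[labs != "ambiguous"]
  groups <- list()
  seen <- character()
  for (lab in labs) {
    members <- strsplit(lab, "+", fixed = TRUE)[[1L]]
    members <- setdiff(members, seen)
    if (length(members) > 0L) {
      groups[[lab]] <- members
      seen <- c(seen, members)
    }
  }
  left <- setdiff(names(sources), seen)
  for (s in left) groups[[s]] <- s
  groups
}
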