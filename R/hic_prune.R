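## Hi-C pair pruning: drop secondary/supplementary records (SAM flag mask
## 2304), drop low-MAPQ pairs, then drop pairs linking allelic unitigs so
## the scaffolder never sees uninformative inter-haplotype links.
## Removal is pair-level: if either mate fails a filter the pair goes.

#' Remove pairs with masked SAM flag bits
#'
#' A pair is removed iff `bitwAnd(flags, mask) != 0` on either mate. The
#' default mask 2304 = 256 (secondary) + 2048 (supplementary).
#'
#' @param pairs contact-pair data.frame.
#' @param mask SAM flag bitmask.
#' @return the surviving pairs.
#' @export
filter_flags <- function(pairs, mask = 2304L) {
  assert_scalar_number(mask, "mask", min = 0)
  mask <- as.integer(mask)
  keep <- bitwAnd(pairs$flags1, mask) == 0L &
    bitwAnd(pairs$flags2, mask) == 0L
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove pairs below a mapping-quality threshold
#'
#' A pair is removed iff `min(mapq1, mapq2) < min_mapq`.
#'
#' @param pairs contact-pair data.frame.
#' @param min_mapq minimum mapping quality (inclusive).
#' @return the surviving pairs.
#' @export
filter_mapq <- function(pairs, min_mapq = 30L) {
  assert_scalar_number(min_mapq, "min_mapq", min = 0)
  keep <- pmin(pairs$mapq1, pairs$mapq2) >= min_mapq
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove pairs linking allelic unitigs
#'
#' A pair is removed iff its two unitigs differ and the unordered pair is
#' in the allelic table. Intra-unitig pairs are always kept by this
#' filter. Pairs referencing a unitig outside the supplied assembly
#' namespace are kept (fail-open) and tallied.
#'
#' @param pairs contact-pair data.frame.
#' @param table an `allelic_table`.
#' @param known_unitigs optional character vector of all assembly unitig
#'   ids; when given, pairs touching unknown unitigs are counted in the
#'   report's `n_unknown`.
#' @return list with elements `pairs` (survivors) and `report`
#'   (a `prune_report`; only the allelic counters are populated).
#' @export
prune_allelic <- function(pairs, table, known_unitigs = NULL) {
  stopifnot(inherits(table, "allelic_table"))
  keys <- pair_key(pairs$uid1, pairs$uid2)
  allelic_keys <- pair_key(table$allelic_pairs$u1, table$allelic_pairs$u2)
  inter <- pairs$uid1 != pairs$uid2
  hit <- inter & keys %in% allelic_keys
  n_unknown <- 0L
  if (!is.null(known_unitigs)) {
    unknown <- !(pairs$uid1 %in% known_unitigs) |
      !(pairs$uid2 %in% known_unitigs)
    n_unknown <- sum(unknown)
    if (n_unknown > 0L) {
      warning(n_unknown, " pair(s) reference unitigs outside the assembly",
              " namespace; kept")
      hit <- hit & !unknown
    }
  }
  removed <- pairs[hit, , drop = FALSE]
  out <- pairs[!hit, , drop = FALSE]
  rownames(out) <- NULL
  rc <- removed_pair_tally(removed)
  report <- new_prune_report(n_input = nrow(pairs), n_flag_removed = 0L,
                             n_mapq_removed = 0L,
                             n_allelic_removed = sum(hit),
                             n_output = nrow(out),
                             removed_pair_counts = rc,
                             n_unknown = n_unknown)
  list(pairs = out, report = report)
}

#' Full Hi-C pruning pipeline
#'
#' Applies the three filters in the order flags, MAPQ, allelic. Each pair
#' is attributed to its first failing filter, so the report counters
#' satisfy `n_input = n_flag_removed + n_mapq_removed +
#' n_allelic_removed + n_output`.
#'
#' @inheritParams prune_allelic
#' @inheritParams filter_flags
#' @inheritParams filter_mapq
#' @return list with elements `pairs` and `report` (a `prune_report`).
#' @export
prune_pipeline <- function(pairs, table, mask = 2304L, min_mapq = 30L,
                           known_unitigs = NULL) {
  n_input <- nrow(pairs)
  p1 <- filter_flags(pairs, mask)
  n_flag <- n_input - nrow(p1)
  p2 <- filter_mapq(p1, min_mapq)
  n_mapq <- nrow(p1) - nrow(p2)
  al <- prune_allelic(p2, table, known_unitigs = known_unitigs)
  report <- new_prune_report(n_input = n_input, n_flag_removed = n_flag,
                             n_mapq_removed = n_mapq,
                             n_allelic_removed = al$report$n_allelic_removed,
                             n_output = nrow(al$pairs),
                             removed_pair_counts =
                               al$report$removed_pair_counts,
                             n_unknown = al$report$n_unknown)
  list(pairs = al$pairs, report = report)
}

removed_pair_tally <- function(removed) {
  if (nrow(removed) == 0L) {
    return(data.frame(u1 = character(), u2 = character(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- pair_key(removed$uid1, removed$uid2)
  tab <- sort(table(key), decreasing = TRUE)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  data.frame(u1 = vapply(parts, `[[`, "", 1L),
             u2 = vapply(parts, `[[`, "", 2L),
             n = as.integer(tab), stringsAsFactors = FALSE)
}

new_prune_report <- function(n_input, n_flag_removed, n_mapq_removed,
                             n_allelic_removed, n_output,
                             removed_pair_counts, n_unknown = 0L) {
  structure(list(n_input = as.integer(n_input),
                 n_flag_removed = as.integer(n_flag_removed),
                 n_mapq_removed = as.integer(n_mapq_removed),
                 n_allelic_removed = as.integer(n_allelic_removed),
                 n_output = as.integer(n_output),
                 removed_pair_counts = removed_pair_counts,
                 n_unknown = as.integer(n_unknown)),
            class = "prune_report")
}

#' @export
print.prune_report <- function(x, ...) {
  cat("Hi-C prune report\n")
  cat("  input pairs:     ", x$n_input, "\n")
  cat("  flag-removed:    ", x$n_flag_removed, "\n")
  cat("  MAPQ-removed:    ", x$n_mapq_removed, "\n")
  cat("  allelic-removed: ", x$n_allelic_removed, "\n")
  cat("  output pairs:    ", x$n_output, "\n")
  if (x$n_unknown > 0L) cat("  unknown-unitig pairs kept:", x$n_unknown, "\n")
  invisible(x)
}

#' Serialize a prune report as JSON
#'
#' Writes the five counters plus the 20 most-removed unitig pairs.
#'
#' @param report a `prune_report`.
#' @param path output path.
#' @export
write_prune_report <- function(report, path) {
  stopifnot(inherits(report, "prune_report"))
  top <- utils::head(report$removed_pair_counts, 20L)
  obj <- list(n_input = report$n_input,
              n_flag_removed = report$n_flag_removed,
              n_mapq_removed = report$n_mapq_removed,
              n_allelic_removed = report$n_allelic_removed,
              n_output = report$n_output,
              n_unknown = report$n_unknown,
              top_removed_pairs = top)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
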