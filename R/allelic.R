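## Allelic-unitig table: unitigs sharing the same single-copy protein
## marker are treated as allelic (inter-haplotype copies of one locus),
## and the induced unitig pairs drive Hi-C link pruning.

#' Deduplicate marker hits per (marker, unitig)
#'
#' Keeps, for every (marker, unitig) combination, the single best hit:
#' maximal bitscore, ties broken by lower e-value, then by input order.
#'
#' @param hits data.frame of marker hits (see [read_tabular_hits()]).
#' @return data.frame with at most one row per (marker, unitig).
#' @export
best_hit_per_marker_unitig <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$marker_id, hits$unitig_id, -hits$bitscore, hits$evalue)
  h <- hits[ord, , drop = FALSE]
  keep <- !duplicated(paste(h$marker_id, h$unitig_id, sep = "\t"))
  out <- h[keep, , drop = FALSE]
  out <- out[order(match(paste(out$marker_id, out$unitig_id, sep = "\t"),
                         paste(hits$marker_id, hits$unitig_id, sep = "\t"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the allelic-unitig table from single-copy marker hits
#'
#' Hits below `min_identity` are discarded. For each marker the set of hit
#' unitigs is recorded; markers hitting more unitigs than the ploidy are
#' flagged as presumed repeat-contaminated and contribute no allelic
#' pairs. All unordered unitig pairs within each remaining multi-unitig
#' set become allelic pairs.
#'
#' @param hits deduplicated marker-hit data.frame
#'   (see [best_hit_per_marker_unitig()]).
#' @param ploidy expected copy number per marker (4 for a phased
#'   tetraploid: one copy per haplotype).
#' @param min_identity minimum percent identity for a hit to count.
#' @return an object of class `allelic_table` with elements
#'   `marker_to_unitigs` (named list of sorted unitig-id vectors),
#'   `allelic_pairs` (data.frame `u1`, `u2` with `u1 < u2`),
#'   `flagged_markers`, `ploidy`, `min_identity`.
#' @export
build_allelic_table <- function(hits, ploidy = 4L, min_identity = 75) {
  if (!is.numeric(ploidy) || length(ploidy) != 1L || ploidy < 2L) {
    stop("ploidy must be a single integer >= 2", call. = FALSE)
  }
  ploidy <- as.integer(ploidy)
  h <- hits[hits$percent_identity >= min_identity, , drop = FALSE]
  sets <- lapply(split(h$unitig_id, h$marker_id),
                 function(u) sort(unique(u)))
  flagged <- names(sets)[lengths(sets) > ploidy]
  pair_sets <- sets[lengths(sets) >= 2L & lengths(sets) <= ploidy]
  if (length(pair_sets) > 0L) {
    pl <- lapply(pair_sets, function(u) {
      cb <- utils::combn(u, 2L)
      data.frame(u1 = cb[1L, ], u2 = cb[2L, ], stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pl)
    pairs <- pairs[!duplicated(paste(pairs$u1, pairs$u2, sep = "\t")), ,
                   drop = FALSE]
    pairs <- pairs[order(pairs$u1, pairs$u2), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(u1 = character(), u2 = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(marker_to_unitigs = sets, allelic_pairs = pairs,
                 flagged_markers = flagged, ploidy = ploidy,
                 min_identity = min_identity),
            class = "allelic_table")
}

#' @export
print.allelic_table <- function(x, ...) {
  cat("Allelic-unitig table\n")
  cat("  markers:       ", length(x$marker_to_unitigs), "\n")
  cat("  allelic pairs: ", nrow(x$allelic_pairs), "\n")
  cat("  flagged (> ploidy ", x$ploidy, "): ",
      length(x$flagged_markers), "\n", sep = "")
  invisible(x)
}

#' Marker copy-number histogram
#'
#' Number of markers by unitig copy count (size of each marker's unitig
#' set); flagged markers are included at their true count. In a fully
#' phased tetraploid the histogram mode is at 4, one copy per haplotype.
#'
#' @param table an `allelic_table`.
#' @return data.frame with columns `copies` (integer) and `n_markers`.
#' @export
copy_number_histogram <- function(table) {
  stopifnot(inherits(table, "allelic_table"))
  n <- lengths(table$marker_to_unitigs)
  if (length(n) == 0L) {
    return(data.frame(copies = integer(), n_markers = integer()))
  }
  tab <- table(n)
  data.frame(copies = as.integer(names(tab)),
             n_markers = as.integer(tab))
}

#' Write an allelic table to TSV
#'
#' Writes two files: `path` with one line per marker (marker id,
#' comma-joined unitig ids, flag column) and `pairs_path` with the induced
#' allelic unitig pairs.
#'
#' @param table an `allelic_table`.
#' @param path output path for the marker table.
#' @param pairs_path output path for the allelic-pairs table (default:
#'   `path` with a `.pairs.tsv` suffix).
#' @export
write_allelic_table <- function(table, path,
                                pairs_path = paste0(path, ".pairs.tsv")) {
  stopifnot(inherits(table, "allelic_table"))
  m <- names(table$marker_to_unitigs)
  lines <- paste(m,
                 vapply(table$marker_to_unitigs, paste, "", collapse = ","),
                 ifelse(m %in% table$flagged_markers, "flagged", "ok"),
                 sep = "\t")
  writeLines(lines, path)
  writeLines(paste(table$allelic_pairs$u1, table$allelic_pairs$u2,
                   sep = "\t"), pairs_path)
  invisible(path)
}

#' Read an allelic table written by [write_allelic_table()]
#'
#' @inheritParams write_allelic_table
#' @param ploidy,min_identity metadata restored onto the object.
#' @return an `allelic_table`.
#' @export
read_allelic_table <- function(path, pairs_path = paste0(path, ".pairs.tsv"),
                               ploidy = 4L, min_identity = 75) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) sort(strsplit(f[2L], ",")[[1L]]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  flagged <- names(sets)[vapply(fields, `[[`, "", 3L) == "flagged"]
  plines <- readLines(pairs_path, warn = FALSE)
  plines <- plines[nzchar(plines)]
  if (length(plines) > 0L) {
    pf <- strsplit(plines, "\t", fixed = TRUE)
    pairs <- data.frame(u1 = vapply(pf, `[[`, "", 1L),
                        u2 = vapply(pf, `[[`, "", 2L),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(u1 = character(), u2 = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(marker_to_unitigs = sets, allelic_pairs = pairs,
                 flagged_markers = flagged, ploidy = as.integer(ploidy),
                 min_identity = min_identity),
            class = "allelic_table")
}
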