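## Readers and writers for the external formats the pipeline touches.
## All internal coordinates are 0-based half-open; 1-based inputs (SAM)
## are converted at the reader boundary. Writers emit LF line endings.

#' Read a FASTA file
#'
#' Returns the sequences as an uppercased [Biostrings::DNAStringSet] in
#' file order. The file is pre-checked so that malformed input produces an
#' error naming the offending line rather than an opaque parser failure.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`, names taken from the header word.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    stop("FASTA format error: ", path, " is empty", call. = FALSE)
  }
  first <- nonempty[1L]
  if (!startsWith(lines[first], ">")) {
    stop("FASTA format error at line ", first,
         ": expected '>' header, got '", substr(lines[first], 1, 20), "'",
         call. = FALSE)
  }
  hdr <- which(startsWith(lines, ">"))
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (any(ids == "" | ids == ">")) {
    bad <- hdr[which(ids == "" | ids == ">")[1L]]
    stop("FASTA format error at line ", bad, ": empty header", call. = FALSE)
  }
  x <- Biostrings::readDNAStringSet(path)
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#'
#' @param seqs a `DNAStringSet` or named character vector.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (!methods::is(seqs, "XStringSet")) {
    seqs <- Biostrings::DNAStringSet(as_seq_chr(seqs))
  }
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read 12-column tabular protein hits
#'
#' Parses the standard tab-separated protein-search hit layout (one hit
#' per line, >= 12 columns): column 1 marker id, column 2 unitig id,
#' column 3 percent identity, column 11 e-value, column 12 bitscore.
#'
#' @param path path to the hits table.
#' @return data.frame with columns `marker_id`, `unitig_id`,
#'   `percent_identity`, `bitscore`, `evalue`, in file order.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines))
  if (length(keep) == 0L) {
    return(data.frame(marker_id = character(), unitig_id = character(),
                      percent_identity = numeric(), bitscore = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- keep[which(nf < 12L)[1L]]
    stop("hits format error at line ", bad, ": fewer than 12 columns",
         call. = FALSE)
  }
  get_col <- function(i) vapply(fields, `[[`, "", i)
  num_col <- function(i, what) {
    v <- suppressWarnings(as.numeric(get_col(i)))
    if (anyNA(v)) {
      bad <- keep[which(is.na(v))[1L]]
      stop("hits format error at line ", bad, ": non-numeric ", what,
           call. = FALSE)
    }
    v
  }
  data.frame(marker_id = get_col(1L), unitig_id = get_col(2L),
             percent_identity = num_col(3L, "identity"),
             bitscore = num_col(12L, "bitscore"),
             evalue = num_col(11L, "evalue"),
             stringsAsFactors = FALSE)
}

#' Read a PAF alignment file
#'
#' Keeps the target interval (PAF columns 6-9, already 0-based half-open)
#' and mapping quality (column 12); optional SAM-style tag columns are
#' ignored. Records with `target_end <= target_start` are rejected with a
#' warning and parsing continues.
#'
#' @param path path to a PAF file.
#' @return data.frame with columns `query_id`, `target_id`,
#'   `target_start`, `target_end`, `mapq`, `flags` (always 0; PAF carries
#'   no SAM flag field).
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  empty <- data.frame(query_id = character(), target_id = character(),
                      target_start = integer(), target_end = integer(),
                      mapq = integer(), flags = integer(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  cols <- scan(path, sep = "\t", quiet = TRUE, flush = TRUE,
               what = list(q = "", ql = "", qs = "", qe = "", strand = "",
                           t = "", tl = "", ts = "", te = "", nm = "",
                           al = "", mq = ""))
  if (length(cols$q) == 0L) return(empty)
  out <- data.frame(query_id = cols$q, target_id = cols$t,
                    target_start = as.integer(cols$ts),
                    target_end = as.integer(cols$te),
                    mapq = as.integer(cols$mq), flags = 0L,
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$target_start) | is.na(out$target_end) |
                 out$target_end <= out$target_start)
  if (length(bad) > 0L) {
    warning(length(bad), " PAF record(s) with empty target interval rejected")
    out <- out[-bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write alignments as PAF
#'
#' Emits minimal 12-column PAF records from internal alignment records;
#' query coordinates are synthesized from the target interval length and
#' the strand is reported as `+` (strand is ignored throughout).
#'
#' @param aln data.frame as returned by [read_paf()].
#' @param path output path.
#' @param target_lengths named vector of target sequence lengths.
#' @export
write_paf <- function(aln, path, target_lengths) {
  len <- aln$target_end - aln$target_start
  tl <- unname(target_lengths[aln$target_id])
  lines <- paste(aln$query_id, len, 0L, len, "+", aln$target_id,
                 as.integer(tl), aln$target_start, aln$target_end,
                 len, len, aln$mapq, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a windowed depth track as bedGraph
#'
#' One line per window; adjacent equal-valued windows are deliberately not
#' merged so the window grid round-trips bit-exactly.
#'
#' @param track data.frame with columns `target_id`, `start`, `end` and a
#'   value column (`depth` or `value`).
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  value <- if ("depth" %in% names(track)) track$depth else track$value
  if (is.null(value)) stop("track needs a 'depth' or 'value' column",
                           call. = FALSE)
  for (tid in unique(track$target_id)) {
    w <- track[track$target_id == tid, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    if (nrow(w) > 1L && any(w$start[-1L] < w$end[-nrow(w)])) {
      stop("overlapping windows on ", tid, call. = FALSE)
    }
  }
  lines <- paste(track$target_id, format(track$start, scientific = FALSE),
                 format(track$end, scientific = FALSE),
                 format(value, scientific = FALSE, trim = TRUE), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file back into a track data.frame
#'
#' @param path path to a 4-column bedGraph file.
#' @return data.frame with columns `target_id`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(target_id = character(), start = integer(),
                      end = integer(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("target_id", "start", "end", "value"),
                         colClasses = c("character", "integer", "integer",
                                        "numeric"))
  x
}

#' Write intervals as BED3
#'
#' @param intervals data.frame with columns `target_id`, `start`, `end`
#'   (0-based half-open).
#' @param path output path.
#' @export
write_bed3 <- function(intervals, path) {
  lines <- paste(intervals$target_id,
                 format(intervals$start, scientific = FALSE),
                 format(intervals$end, scientific = FALSE), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a 7-column Hi-C pairs table
#'
#' Dependency-free pairs dialect: tab-separated `read_id, uid1, pos1,
#' mapq1, uid2, pos2, mapq2` with 0-based positions. The dialect carries
#' no SAM flag field, so both flag fields are 0 on read.
#'
#' @param path path to the pairs table; lines starting with `#` skipped.
#' @return contact-pair data.frame (`read_id`, `uid1`, `pos1`, `mapq1`,
#'   `flags1`, `uid2`, `pos2`, `mapq2`, `flags2`).
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(empty_pairs_df())
  cols <- scan(path, sep = "\t", quiet = TRUE, flush = TRUE,
               comment.char = "#",
               what = list(r = "", u1 = "", p1 = 0L, q1 = 0L,
                           u2 = "", p2 = 0L, q2 = 0L))
  if (length(cols$r) == 0L) return(empty_pairs_df())
  data.frame(read_id = cols$r, uid1 = cols$u1, pos1 = cols$p1,
             mapq1 = cols$q1, flags1 = 0L, uid2 = cols$u2, pos2 = cols$p2,
             mapq2 = cols$q2, flags2 = 0L, stringsAsFactors = FALSE)
}

#' Write Hi-C pairs in the 7-column pairs dialect
#'
#' @param pairs contact-pair data.frame.
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  lines <- paste(pairs$read_id, pairs$uid1, pairs$pos1, pairs$mapq1,
                 pairs$uid2, pairs$pos2, pairs$mapq2, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read Hi-C pairs from a name-sorted SAM record stream
#'
#' Parses SAM text records (header lines skipped) and pairs the records of
#' each read name; the stream is expected to be name-sorted with exactly
#' two records per read. Reads with a different record count are skipped
#' and tallied in the `n_unpaired` attribute. SAM 1-based positions are
#' converted to 0-based; flags and MAPQ are retained per mate.
#'
#' @param path path to a SAM file (text).
#' @return contact-pair data.frame with attribute `n_unpaired`.
#' @export
read_pairs_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0L) {
    out <- empty_pairs_df()
    attr(out, "n_unpaired") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L)) {
    bad <- which(lengths(fields) < 11L)[1L]
    stop("SAM format error at record ", bad, ": fewer than 11 fields",
         call. = FALSE)
  }
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L)) - 1L
  mapq <- as.integer(vapply(fields, `[[`, "", 5L))
  cnt <- table(qname)
  good <- names(cnt)[cnt == 2L]
  n_unpaired <- length(cnt) - length(good)
  keep <- qname %in% good
  qname <- qname[keep]; flag <- flag[keep]; rname <- rname[keep]
  pos <- pos[keep]; mapq <- mapq[keep]
  ord <- order(match(qname, unique(qname)))  # preserve stream order
  first <- ord[seq(1L, length(ord), by = 2L)]
  second <- ord[seq(2L, length(ord), by = 2L)]
  out <- data.frame(read_id = qname[first], uid1 = rname[first],
                    pos1 = pos[first], mapq1 = mapq[first],
                    flags1 = flag[first], uid2 = rname[second],
                    pos2 = pos[second], mapq2 = mapq[second],
                    flags2 = flag[second], stringsAsFactors = FALSE)
  attr(out, "n_unpaired") <- as.integer(n_unpaired)
  out
}
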