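## Curation tracks: N-gap intervals and telomere-motif density, the two
## sequence-derived overlays used when inspecting a contact map by hand.

#' Find N-gap intervals
#'
#' All maximal runs of `N` of length >= `min_run`, per sequence, in
#' coordinate order (0-based half-open).
#'
#' @param sequences a `DNAStringSet` or named character vector.
#' @param min_run minimum run length in bp ("gaps over 10 bp" means
#'   length >= 10 here, matching the `-n` semantics of the usual gap
#'   scanner).
#' @return data.frame with columns `target_id`, `start`, `end`.
#' @export
find_gaps <- function(sequences, min_run = 10L) {
  assert_scalar_number(min_run, "min_run", min = 1)
  seqs <- as_seq_chr(sequences)
  out <- lapply(names(seqs), function(id) {
    m <- gregexpr(sprintf("N{%d,}", as.integer(min_run)), seqs[[id]])[[1L]]
    if (m[1L] == -1L) {
      return(data.frame(target_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    }
    start <- as.integer(m) - 1L
    data.frame(target_id = id, start = start,
               end = start + attr(m, "match.length"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Telomere-motif density track
#'
#' Counts, per window, occurrences of the motif plus occurrences of its
#' reverse complement whose start position falls in the window;
#' overlapping occurrences are counted. The default motif is the plant
#' telomere repeat `TTTAGGG` (reverse complement `CCCTAAA`).
#'
#' @param sequences a `DNAStringSet` or named character vector.
#' @param motif exact motif to scan for (no mismatches).
#' @param window window size in bp (>= motif length).
#' @return track data.frame with columns `target_id`, `start`, `end`,
#'   `count`.
#' @export
telomere_density <- function(sequences, motif = "TTTAGGG",
                             window = 10000L) {
  stopifnot(is.character(motif), length(motif) == 1L, nzchar(motif))
  motif <- toupper(motif)
  assert_scalar_number(window, "window", min = nchar(motif))
  window <- as.integer(window)
  rc <- revcomp(motif)
  seqs <- as_seq_chr(sequences)
  out <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    len <- nchar(s)
    starts0 <- motif_starts(s, motif)
    if (rc != motif) starts0 <- c(starts0, motif_starts(s, rc))
    wstart <- seq.int(0L, max(len - 1L, 0L), by = window)
    wend <- pmin(wstart + window, len)
    count <- if (length(starts0) > 0L) {
      tabulate(starts0 %/% window + 1L, nbins = length(wstart))
    } else {
      integer(length(wstart))
    }
    data.frame(target_id = id, start = wstart, end = wend,
               count = count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## 0-based start positions of (possibly overlapping) exact motif matches.
motif_starts <- function(seq, motif) {
  pat <- sprintf("(?=%s)", motif)
  m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer())
  as.integer(m) - 1L
}
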