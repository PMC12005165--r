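#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper used by the motif scanner and the
#' k-mer canonicalization oracle; IUPAC ambiguity codes are complemented
#' like `Biostrings` does.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Canonical unordered pair key "min\tmax"; vectorized.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

## Stage-specific RNG seed derived from a master seed; keeps values well
## below .Machine$integer.max for any small master seed.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage)
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("'%s' must be a single number >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}

## Coerce sequences to a named uppercase character vector; accepts a
## DNAStringSet or a named character vector.
as_seq_chr <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- toupper(as.character(x))
  } else if (is.character(x)) {
    out <- toupper(x)
  } else {
    stop("sequences must be a DNAStringSet or named character vector",
         call. = FALSE)
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("sequences must be named", call. = FALSE)
  }
  out
}

empty_pairs_df <- function() {
  data.frame(read_id = character(), uid1 = character(), pos1 = integer(),
             mapq1 = integer(), flags1 = integer(), uid2 = character(),
             pos2 = integer(), mapq2 = integer(), flags2 = integer(),
             stringsAsFactors = FALSE)
}
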