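## Coverage-based subgenome ancestry: windowed depth of candidate
## progenitor read alignments, per-source normalization, chromosome-level
## assignment with an either/or combined label for indistinguishable
## progenitors, and run-length switch detection for homoeologous
## exchanges and translocations.

#' Windowed mean read depth per target
#'
#' Per window, mean per-base depth = sum of alignment overlap lengths
#' divided by the window size (the final, possibly short, window uses its
#' true size). Windows tile `[0, target_length)`.
#'
#' @param alignments alignment data.frame (see [read_paf()]).
#' @param target_lengths named numeric vector of target lengths (bp).
#' @param window window size in bp.
#' @return track data.frame with columns `target_id`, `start`, `end`,
#'   `depth`; attribute `n_unknown` tallies alignments to targets absent
#'   from `target_lengths`.
#' @export
windowed_depth <- function(alignments, target_lengths, window = 100000L) {
  assert_scalar_number(window, "window", min = 1)
  window <- as.integer(window)
  ids <- names(target_lengths)
  if (is.null(ids)) stop("target_lengths must be named", call. = FALSE)
  known <- alignments$target_id %in% ids
  n_unknown <- sum(!known)
  if (n_unknown > 0L) {
    warning(n_unknown, " alignment(s) to unknown targets ignored")
  }
  aln <- alignments[known, , drop = FALSE]
  tracks <- lapply(ids, function(tid) {
    len <- as.integer(target_lengths[[tid]])
    starts <- seq.int(0L, len - 1L, by = window)
    ends <- pmin(starts + window, len)
    a <- aln[aln$target_id == tid, , drop = FALSE]
    if (nrow(a) == 0L) {
      depth <- numeric(length(starts))
    } else {
      ir <- IRanges::IRanges(start = pmax(a$target_start, 0L) + 1L,
                             end = pmin(a$target_end, len))
      cov <- IRanges::coverage(ir, width = len)
      v <- IRanges::Views(cov, start = starts + 1L, end = ends)
      depth <- IRanges::viewSums(v) / (ends - starts)
    }
    data.frame(target_id = tid, start = starts, end = ends,
               depth = as.numeric(depth), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tracks)
  rownames(out) <- NULL
  attr(out, "n_unknown") <- n_unknown
  out
}

#' Windowed depth tracks for several progenitor sources
#'
#' @param alignments_by_source named list of alignment data.frames, one
#'   per candidate progenitor.
#' @inheritParams windowed_depth
#' @return long track data.frame with an extra `source` column.
#' @export
depth_tracks <- function(alignments_by_source, target_lengths,
                         window = 100000L) {
  stopifnot(is.list(alignments_by_source),
            !is.null(names(alignments_by_source)))
  out <- lapply(names(alignments_by_source), function(src) {
    tr <- windowed_depth(alignments_by_source[[src]], target_lengths,
                         window)
    tr$source <- src
    tr
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Normalize depth tracks per source
#'
#' Divides each source's depths by a genome-wide per-source constant so
#' that the expected on-target value is about 1 and sources with
#' different sequencing depths become comparable. The constant is the
#' median of the nonzero windows at or above that source's mean nonzero
#' depth: for a progenitor that covers only part of the assembly the
#' window-depth distribution is bimodal (on-target vs off-target mode),
#' and this statistic locks onto the on-target mode even when the two
#' modes hold equally many windows, where a plain median would sit
#' unstably between them. For a source of uniform depth it reduces to
#' the plain median.
#'
#' @param tracks long track data.frame with a `source` column.
#' @return tracks with normalized `depth`.
#' @export
normalize_tracks <- function(tracks) {
  stopifnot("source" %in% names(tracks))
  for (src in unique(tracks$source)) {
    i <- tracks$source == src
    nz <- tracks$depth[i][tracks$depth[i] > 0]
    if (length(nz) == 0L) {
      stop("source '", src, "' has no nonzero depth windows; cannot ",
           "normalize", call. = FALSE)
    }
    const <- median(nz[nz >= mean(nz)])
    tracks$depth[i] <- tracks$depth[i] / const
  }
  tracks
}

#' Assign each target to a progenitor subgenome
#'
#' For each target, sources are ranked by median normalized depth. The
#' call is the best source when its median exceeds the runner-up by
#' `margin_threshold`; sources that are mutually indistinguishable
#' (within the margin of each other) but jointly above the rest are
#' reported as a combined `"a+b"` label. When all sources are within the
#' margin the call is `"ambiguous"`.
#'
#' @param tracks normalized long track data.frame (>= 2 sources).
#' @param margin_threshold ratio of best to second-best (or best group to
#'   best outsider) required for a call.
#' @return data.frame with one row per target: `target_id`,
#'   `assigned_source`, `margin`, and one `median_<source>` column per
#'   source.
#' @export
assign_subgenomes <- function(tracks, margin_threshold = 2.0) {
  stopifnot("source" %in% names(tracks))
  sources <- sort(unique(tracks$source))
  if (length(sources) < 2L) stop(">= 2 sources required", call. = FALSE)
  targets <- unique(tracks$target_id)
  rows <- lapply(targets, function(tid) {
    tt <- tracks[tracks$target_id == tid, , drop = FALSE]
    med <- vapply(sources, function(s) {
      median(tt$depth[tt$source == s])
    }, 0.0)
    ord <- order(-med, sources)
    m <- med[ord]
    in_group <- m[1L] < margin_threshold * m | (m[1L] == 0 & m == 0)
    group <- sources[ord][in_group]
    rest <- m[!in_group]
    if (length(rest) == 0L) {
      assigned <- "ambiguous"
      margin <- NA_real_
    } else {
      margin <- if (max(rest) > 0) min(m[in_group]) / max(rest) else Inf
      assigned <- if (margin >= margin_threshold) {
        paste(sort(group), collapse = "+")
      } else {
        "ambiguous"
      }
      if (assigned == "ambiguous") margin <- NA_real_
    }
    out <- data.frame(target_id = tid, assigned_source = assigned,
                      margin = margin, stringsAsFactors = FALSE)
    for (s in sources) out[[paste0("median_", s)]] <- unname(med[s])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combine depth tracks of indistinguishable sources
#'
#' Sums normalized depths of the sources in each group window-by-window;
#' used before switch detection when two candidate progenitors cannot be
#' told apart and act as one subgenome signal.
#'
#' @param tracks long track data.frame.
#' @param groups named list mapping a new label to the character vector
#'   of source names it absorbs.
#' @return long track data.frame with the group labels as sources.
#' @export
combine_tracks <- function(tracks, groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  out <- lapply(names(groups), function(lab) {
    tt <- tracks[tracks$source %in% groups[[lab]], , drop = FALSE]
    agg <- stats::aggregate(depth ~ target_id + start + end, data = tt,
                            FUN = sum)
    agg$source <- lab
    agg[order(agg$target_id, agg$start),
        c("target_id", "start", "end", "depth", "source")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect coverage-switch segments per target
#'
#' Per window the dominant source is the argmax of normalized depth (ties
#' broken by source name). Runs of identical dominance shorter than
#' `min_segment` windows are merged into the flanking majority, and the
#' remaining runs are emitted as segments tiling the target. Targets
#' whose segments carry more than one distinct dominant source are
#' candidate rearrangements (homoeologous exchange or translocation).
#'
#' @param tracks normalized long track data.frame (>= 2 sources).
#' @param min_segment minimum run length in windows.
#' @return data.frame of segments (`target_id`, `start`, `end`,
#'   `dominant_source`), ordered within target.
#' @export
detect_switches <- function(tracks, min_segment = 10L) {
  stopifnot("source" %in% names(tracks))
  sources <- sort(unique(tracks$source))
  if (length(sources) < 2L) stop(">= 2 sources required", call. = FALSE)
  targets <- unique(tracks$target_id)
  segs <- lapply(targets, function(tid) {
    tt <- tracks[tracks$target_id == tid, , drop = FALSE]
    wide <- vapply(sources, function(s) {
      w <- tt[tt$source == s, , drop = FALSE]
      w$depth[order(w$start)]
    }, numeric(sum(tt$source == sources[1L])))
    grid <- tt[tt$source == sources[1L], , drop = FALSE]
    grid <- grid[order(grid$start), , drop = FALSE]
    dom <- sources[max.col(wide, ties.method = "first")]
    dom <- merge_short_runs(dom, min_segment)
    r <- rle(dom)
    endw <- cumsum(r$lengths)
    startw <- c(1L, endw[-length(endw)] + 1L)
    data.frame(target_id = tid, start = grid$start[startw],
               end = grid$end[endw], dominant_source = r$values,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

## Merge runs shorter than min_segment into the flanking majority: each
## short run is relabelled to the label of its longer flanking run
## (left-biased on ties, terminal runs take their only neighbour),
## iterating from the shortest run until every run is long enough.
merge_short_runs <- function(labels, min_segment) {
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1L) return(labels)
    short <- which(r$lengths < min_segment)
    if (length(short) == 0L) return(labels)
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1L) r$lengths[i - 1L] else -1L
    right <- if (i < length(r$lengths)) r$lengths[i + 1L] else -1L
    j <- if (left >= right) i - 1L else i + 1L
    r$values[i] <- r$values[j]
    labels <- inverse.rle(r)
  }
}

#' Targets showing more than one dominant source
#'
#' @param segments output of [detect_switches()].
#' @return character vector of flagged target ids.
#' @export
flagged_targets <- function(segments) {
  n <- tapply(segments$dominant_source, segments$target_id,
              function(x) length(unique(x)))
  names(n)[n > 1L]
}
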