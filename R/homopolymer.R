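## Homopolymer / short-tandem-repeat adjacency detection for indel sites.
##
## An indel is considered repeat-adjacent when a mononucleotide run of at
## least `min_run` bases (default 6, i.e. "longer than five"), or a tandem
## repeat (unit 2-6 bp, at least 3 copies), lies within `tol` bases of the
## indel's anchor position in its reference context. gap = 0 means the
## anchor is inside the feature, gap = 1 means it directly abuts it.

#' Find mononucleotide runs in a sequence
#'
#' @param seq DNA string.
#' @param min_run minimum run length to report.
#' @return `data.table` with `start`, `end` (1-based inclusive), `base`,
#'   `length`.
#' @export
find_homopolymer_runs <- function(seq, min_run = 6L) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_run
  data.table(start = starts[keep], end = ends[keep],
             base = r$values[keep], length = r$lengths[keep])
}

#' Find short tandem repeats in a sequence
#'
#' Exhaustive scan for maximal tandem arrays with unit length in
#' `unit_range` and at least `min_copies` exact copies. Arrays whose unit is
#' itself a mononucleotide are excluded (those are homopolymers).
#'
#' @param seq DNA string.
#' @param unit_range integer range of repeat unit lengths (default 2:6).
#' @param min_copies minimum exact copy count (default 3).
#' @return `data.table` with `start`, `end`, `unit`, `copies`.
#' @export
find_tandem_repeats <- function(seq, unit_range = 2:6, min_copies = 3L) {
  s <- toupper(seq)
  n <- nchar(s)
  hits <- list()
  for (u in unit_range) {
    if (2L * u > n) break
    i <- 1L
    while (i + u - 1L <= n) {
      unit <- substr(s, i, i + u - 1L)
      if (length(unique(strsplit(unit, "")[[1L]])) == 1L) { i <- i + 1L; next }
      copies <- 1L
      while (i + (copies + 1L) * u - 1L <= n &&
             substr(s, i + copies * u, i + (copies + 1L) * u - 1L) == unit) {
        copies <- copies + 1L
      }
      if (copies >= min_copies) {
        hits[[length(hits) + 1L]] <-
          data.table(start = i, end = i + copies * u - 1L, unit = unit, copies = copies)
        i <- i + copies * u
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(hits)) {
    return(data.table(start = integer(), end = integer(),
                      unit = character(), copies = integer()))
  }
  unique(rbindlist(hits))
}

feature_gap <- function(pos, start, end) pmax(start - pos, pos - end, 0L)

#' Is an indel adjacent to a homopolymer or short tandem repeat?
#'
#' @param context reference sequence around the indel.
#' @param pos 1-based position of the indel anchor (the left-normalized
#'   coordinate) within `context`.
#' @param min_run minimum homopolymer run length (default 6).
#' @param tol adjacency tolerance in bases: the feature must include the
#'   anchor or come within `tol` bases of it (default 1 = directly abutting).
#' @param unit_range,min_copies tandem-repeat definition
#'   (see [find_tandem_repeats()]).
#' @return logical scalar.
#' @export
is_repeat_adjacent <- function(context, pos, min_run = 6L, tol = 1L,
                               unit_range = 2:6, min_copies = 3L) {
  if (is.na(context) || !nzchar(context)) vk_stop("empty indel context")
  if (pos < 1L || pos > nchar(context)) {
    vk_stop("indel anchor %d outside context of length %d", pos, nchar(context))
  }
  runs <- find_homopolymer_runs(context, min_run)
  if (nrow(runs) && any(feature_gap(pos, runs$start, runs$end) <= tol)) return(TRUE)
  reps <- find_tandem_repeats(context, unit_range, min_copies)
  nrow(reps) > 0L && any(feature_gap(pos, reps$start, reps$end) <= tol)
}
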