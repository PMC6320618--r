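#' Parallel (row-wise) set operations
#'
#' These operators combine the i-th range of `x` with the i-th range of `y`,
#' so both tables must have the same number of rows and each pair must share
#' a seqname. Metadata, strand and genome come from `x`. The family:
#'
#' * `x %intersect% y` — `[max(starts), min(ends)]`; an abutting pair yields
#'   a legal width-0 range, a truly gapped pair is an error.
#' * `x %union% y` — `[min(starts), max(ends)]`, but only when the pair
#'   overlaps or abuts; a gapped pair is an error.
#' * `span(x, y)` — the union that also fills any gap (never errors).
#' * `between(x, y)` — the gap separating the pair,
#'   `[min(ends) + 1, max(starts) - 1]`; width 0 when the pair is adjacent,
#'   and clamped to a width-0 range at `min(ends) + 1` when the pair
#'   overlaps (there is no gap).
#' * `x %setdiff% y` — the bases of `x_i` not in `y_i`, which must form a
#'   single contiguous range: `y_i` strictly inside `x_i` is an error (use
#'   [setdiff_ranges()] for the general, merging case).
#'
#' @param x,y `RangeTable`s of equal length, pairs on the same seqname.
#' @return A `RangeTable` with `x`'s metadata.
#' @examples
#' a <- range_table("chr1", 1, 10)
#' b <- range_table("chr1", 5, 20)
#' a %intersect% b   # [5, 10]
#' span(range_table("chr1", 1, 5), range_table("chr1", 10, 12))     # [1, 12]
#' between(range_table("chr1", 1, 5), range_table("chr1", 10, 12))  # [6, 9]
#' @name parallel-ops
NULL

check_pairs <- function(x, y) {
  stopifnot(inherits(x, "RangeTable"), inherits(y, "RangeTable"))
  if (nrow(x) != nrow(y)) {
    rt_stop(sprintf("parallel operation needs equal lengths (%d vs %d)",
                    nrow(x), nrow(y)), "rt_pairing_error")
  }
  bad <- which(x$seqnames != y$seqnames)
  if (length(bad)) {
    rt_stop(sprintf("row %d: pair is on different sequences ('%s' vs '%s')",
                    bad[1L], x$seqnames[bad[1L]], y$seqnames[bad[1L]]),
            "rt_pairing_error")
  }
  invisible(NULL)
}

with_coords <- function(x, start, end) {
  df <- as.data.frame(x)
  df$start <- as.integer(start)
  df$end <- as.integer(end)
  new_range_table(df, genome_info = get_genome_info(x))
}

#' @rdname parallel-ops
#' @export
`%intersect%` <- function(x, y) {
  check_pairs(x, y)
  s <- pmax(x$start, y$start)
  e <- pmin(x$end, y$end)
  bad <- which(s > e + 1L)
  if (length(bad)) {
    rt_stop(sprintf("row %d: ranges [%d,%d] and [%d,%d] are disjoint",
                    bad[1L], x$start[bad[1L]], x$end[bad[1L]],
                    y$start[bad[1L]], y$end[bad[1L]]), "rt_pairing_error")
  }
  with_coords(x, s, e)
}

#' @rdname parallel-ops
#' @export
`%union%` <- function(x, y) {
  check_pairs(x, y)
  gap <- which(pmax(x$start, y$start) > pmin(x$end, y$end) + 1L)
  if (length(gap)) {
    rt_stop(sprintf("row %d: ranges have a gap; use span() to fill it", gap[1L]),
            "rt_pairing_error")
  }
  with_coords(x, pmin(x$start, y$start), pmax(x$end, y$end))
}

#' @rdname parallel-ops
#' @export
span <- function(x, y) {
  check_pairs(x, y)
  with_coords(x, pmin(x$start, y$start), pmax(x$end, y$end))
}

#' @rdname parallel-ops
#' @export
between <- function(x, y) {
  check_pairs(x, y)
  s <- pmin(x$end, y$end) + 1L
  e <- pmax(pmax(x$start, y$start) - 1L, s - 1L)
  with_coords(x, s, e)
}

#' @rdname parallel-ops
#' @export
`%setdiff%` <- function(x, y) {
  check_pairs(x, y)
  os <- pmax(x$start, y$start)
  oe <- pmin(x$end, y$end)
  no_overlap <- os > oe
  inside <- y$start > x$start & y$end < x$end & !no_overlap
  if (any(inside)) {
    rt_stop(sprintf(paste0("row %d: the difference would be two ranges ",
                           "(subject strictly inside query); use setdiff_ranges()"),
                    which(inside)[1L]), "rt_pairing_error")
  }
  covers <- y$start <= x$start & y$end >= x$end
  s <- x$start
  e <- x$end
  # trimmed from the left when y covers x's start, from the right otherwise
  left_trim <- !no_overlap & !covers & y$start <= x$start
  right_trim <- !no_overlap & !covers & !left_trim
  s[left_trim] <- y$end[left_trim] + 1L
  e[right_trim] <- y$start[right_trim] - 1L
  e[covers] <- s[covers] - 1L   # fully covered: width-0 remnant at x's start
  with_coords(x, s, e)
}
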