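#' Anchoring: fix a point of each range before changing its width
#'
#' The `start`, `end` and `width` of a range are mutually dependent, so
#' changing the width is ambiguous until you say which point stays put.
#' Anchoring records that fixed point as metadata — the coordinates are
#' untouched until a `width` mutation or [stretch()] is applied, at which
#' moment:
#'
#' * `anchor_start()`: `end = start + width - 1` (start stationary);
#' * `anchor_end()`: `start = end - width + 1`;
#' * `anchor_center()`: the midpoint is invariant; when the width change is
#'   odd the extra base goes to the end side (deterministic parity rule);
#' * `anchor_5p()` / `anchor_3p()`: resolve per row to the start or end
#'   according to strand (on the minus strand the 5' end is `end`);
#'   unstranded rows are treated as plus strand.
#'
#' Re-anchoring simply replaces the anchor; [unanchor()] drops it. After a
#' width mutation the result is an ordinary (unanchored) `RangeTable`.
#'
#' @param x A `RangeTable`.
#' @return An anchored `RangeTable` (class `AnchoredRanges`).
#' @examples
#' rng <- range_table("chr1", start = 100, end = 101)
#' mutate(anchor_center(rng), width = 4)   # [99, 102]
#' mutate(anchor_start(rng), width = 10)   # [100, 109]
#' @name anchoring
NULL

ANCHORS <- c("start", "end", "center", "5p", "3p")

set_anchor <- function(x, point) {
  stopifnot(inherits(x, "RangeTable"), point %in% ANCHORS)
  x <- unanchor(x)
  attr(x, "anchor") <- point
  class(x) <- c("AnchoredRanges", class(x))
  x
}

#' @rdname anchoring
#' @export
anchor_start <- function(x) set_anchor(x, "start")

#' @rdname anchoring
#' @export
anchor_end <- function(x) set_anchor(x, "end")

#' @rdname anchoring
#' @export
anchor_center <- function(x) set_anchor(x, "center")

#' @rdname anchoring
#' @export
anchor_5p <- function(x) set_anchor(x, "5p")

#' @rdname anchoring
#' @export
anchor_3p <- function(x) set_anchor(x, "3p")

#' @rdname anchoring
#' @export
anchor <- function(x) attr(x, "anchor", exact = TRUE)

#' @rdname anchoring
#' @export
unanchor <- function(x) {
  attr(x, "anchor") <- NULL
  class(x) <- setdiff(class(x), "AnchoredRanges")
  x
}

#' @rdname range-verbs
#' @export
mutate.AnchoredRanges <- function(.data, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  point <- anchor(.data)
  mutate_impl(unanchor(.data), exprs, parent.frame(), anchor = point)
}

# Core anchored width rule. `w` is a non-negative integer vector (length n).
# Returns new start/end; validation happens in the caller.
apply_anchor_width <- function(start, end, strand, point, w) {
  eff <- rep(point, length(start))
  if (point == "5p") eff <- ifelse(strand == "-", "end", "start")
  if (point == "3p") eff <- ifelse(strand == "-", "start", "end")
  new_start <- start
  new_end <- end
  i <- eff == "start"
  new_end[i] <- start[i] + w[i] - 1L
  i <- eff == "end"
  new_start[i] <- end[i] - w[i] + 1L
  i <- eff == "center"
  if (any(i)) {
    delta <- w[i] - (end[i] - start[i] + 1L)
    left <- delta %/% 2L               # extra base (odd delta) goes end-side
    new_start[i] <- start[i] - left
    new_end[i] <- end[i] + (delta - left)
  }
  list(start = new_start, end = new_end)
}

#' Stretch: anchored adjustment of width
#'
#' Adds `extend` bases to each range's width, holding the anchor point fixed.
#' Unanchored input assumes the midpoint, the conventional default for
#' symmetric extension; negative `extend` shrinks (down to width 0). Width-0
#' ranges are allowed and grow around their insertion point.
#'
#' @param x A `RangeTable`, anchored or not.
#' @param extend Integer number of bases to add to the width (scalar or
#'   per-row); may be negative.
#' @return An unanchored `RangeTable`.
#' @examples
#' stretch(anchor_center(range_table("chr1", 10, 19)), 10)  # [5, 24]
#' stretch(anchor_start(range_table("chr1", 10, 19)), 5)    # [10, 24]
#' @export
stretch <- function(x, extend) {
  point <- anchor(x) %||% "center"
  x <- unanchor(x)
  n <- nrow(x)
  extend <- as.integer(recycle_to(extend, n, "extend"))
  w <- ranges_width(x) + extend
  if (any(w < 0L)) {
    rt_stop(sprintf("row %d: stretching by %d would make the width negative",
                    which(w < 0L)[1L], extend[which(w < 0L)[1L]]),
            "rt_integrity_error")
  }
  se <- apply_anchor_width(x$start, x$end, x$strand, point, w)
  df <- as.data.frame(x)
  df$start <- se$start
  df$end <- se$end
  restore_groups(new_range_table(df, genome_info = get_genome_info(x)), x)
}
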