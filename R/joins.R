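#' Hit generation: overlap and proximity matching
#'
#' `find_overlap_hits()` returns the pairs of row indices (1-based) of `x`
#' and `y` whose ranges lie on the same sequence and share at least one base.
#' Options compose restrictions: `within` keeps only pairs where the query is
#' entirely inside the subject; `directed` requires equal strand (under
#' directed matching an unstranded row matches only unstranded rows; by
#' default strand is ignored entirely); `maxgap` relaxes the share-a-base
#' rule so that pairs separated by at most `maxgap` bases also match
#' (`maxgap = 0` admits abutting ranges; the default `-1` does not — mere
#' adjacency is not an overlap).
#'
#' `find_nearest_hits()` returns at most one hit per query row: the subject
#' with the smallest gap (an overlapping subject has gap 0), ties broken by
#' the lowest subject index. `mode = "precede"` restricts candidates to
#' subjects strictly starting after the query's end (the query precedes
#' them); `mode = "follow"` to subjects strictly ending before the query's
#' start. Proximity is purely coordinate-based; compose with `directed`
#' matching via a strand filter if needed.
#'
#' The matcher prunes candidates against subject starts sorted per sequence;
#' its contract is agreement with the naive quadratic oracle ([oracle_hits()]).
#'
#' @param x,y `RangeTable`s (query and subject).
#' @param within,directed Logical flags, see Details.
#' @param maxgap Integer; largest separating gap still considered a match.
#' @param mode One of `"nearest"`, `"precede"`, `"follow"`.
#' @return A data.frame of class `RangeHits` with columns `query` and
#'   `subject`, sorted by (query, subject), pairs unique.
#' @examples
#' x <- range_table("chr1", 10, 15)
#' y <- range_table("chr1", c(1, 18), c(5, 25))
#' find_nearest_hits(x, y)                 # subject 2 (gap 2 beats gap 4)
#' find_nearest_hits(x, y, mode = "follow")  # subject 1
#' @export
find_overlap_hits <- function(x, y, within = FALSE, directed = FALSE,
                              maxgap = -1L) {
  stopifnot(inherits(x, "RangeTable"), inherits(y, "RangeTable"))
  maxgap <- as.integer(maxgap)
  q_all <- integer(); s_all <- integer()
  for (sq in unique(x$seqnames)) {
    qi <- which(x$seqnames == sq)
    si <- which(y$seqnames == sq)
    if (!length(qi) || !length(si)) next
    o <- order(y$start[si], method = "radix")
    si <- si[o]
    ys <- y$start[si]; ye <- y$end[si]
    for (i in qi) {
      k <- findInterval(x$end[i] + maxgap + 1L, ys)   # ys[j] <= end_i + gap + 1
      if (k == 0L) next
      cand <- seq_len(k)
      ok <- ye[cand] >= x$start[i] - maxgap - 1L
      if (within) ok <- ok & ys[cand] <= x$start[i] & ye[cand] >= x$end[i]
      if (directed) ok <- ok & y$strand[si[cand]] == x$strand[i]
      hits <- si[cand[ok]]
      q_all <- c(q_all, rep(i, length(hits)))
      s_all <- c(s_all, hits)
    }
  }
  new_hits(q_all, s_all)
}

new_hits <- function(q, s) {
  o <- stable_order(q, s)
  structure(data.frame(query = q[o], subject = s[o]),
            class = c("RangeHits", "data.frame"))
}

#' @rdname find_overlap_hits
#' @export
find_nearest_hits <- function(x, y, mode = c("nearest", "precede", "follow")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "RangeTable"), inherits(y, "RangeTable"))
  q_all <- integer(); s_all <- integer()
  for (i in seq_len(nrow(x))) {
    si <- which(y$seqnames == x$seqnames[i])
    if (mode == "precede") si <- si[y$start[si] > x$end[i]]
    if (mode == "follow") si <- si[y$end[si] < x$start[i]]
    if (!length(si)) next
    gap <- pmax(0L, pmax(x$start[i], y$start[si]) - pmin(x$end[i], y$end[si]) - 1L)
    best <- si[which.min(gap)]   # which.min takes the first (lowest index) tie
    q_all <- c(q_all, i)
    s_all <- c(s_all, best)
  }
  new_hits(q_all, s_all)
}

# Combine x coordinates (or supplied ones) with metadata of both sides.
# Name collisions between the two metadata sets get ".x"/".y" suffixes on
# both columns; the coordinate columns never collide because only one set of
# coordinates survives.
join_assemble <- function(x, y, qidx, sidx, start = NULL, end = NULL,
                          suffix = c(".x", ".y")) {
  xm <- meta_cols(x)
  ym <- meta_cols(y)
  shared <- intersect(names(xm), names(ym))
  names(xm)[match(shared, names(xm))] <- paste0(shared, suffix[1L])
  names(ym)[match(shared, names(ym))] <- paste0(shared, suffix[2L])
  df <- as.data.frame(x)[qidx, CORE_COLS, drop = FALSE]
  if (!is.null(start)) { df$start <- as.integer(start); df$end <- as.integer(end) }
  out <- cbind(df, xm[qidx, , drop = FALSE], ym[sidx, , drop = FALSE])
  rownames(out) <- NULL
  new_range_table(out, genome_info = get_genome_info(x))
}

#' Overlap joins: merge two range tables by positional overlap
#'
#' Relational joins keyed on overlap rather than identity. A hit set is
#' computed with [find_overlap_hits()] and consumed by one of three merge
#' modes:
#'
#' * `join_overlap_inner()` — one row per hit, carrying the **x** range's
#'   coordinates and the metadata of both sides (a query hit k times appears
#'   k times);
#' * `join_overlap_intersect()` — as inner, but each row's coordinates are
#'   the intersection `[max(starts), min(ends)]` of the pair;
#' * `join_overlap_left()` — every `x` row appears at least once; rows with
#'   no hit carry `NA` in the columns that came from `y`.
#'
#' `join_nearest()`, `join_precede()` and `join_follow()` merge instead by
#' proximity ([find_nearest_hits()]); queries without a candidate are
#' dropped.
#'
#' @inheritParams find_overlap_hits
#' @param suffix Length-2 suffixes disambiguating colliding metadata names.
#' @return A `RangeTable`; rows ordered by (query row, subject row).
#' @examples
#' x <- range_table("chr1", c(1, 8), c(5, 10))
#' y <- range_table("chr1", 4, 9, id = "g1")
#' join_overlap_inner(x, y)
#' @export
join_overlap_inner <- function(x, y, within = FALSE, directed = FALSE,
                               maxgap = -1L, suffix = c(".x", ".y")) {
  h <- find_overlap_hits(x, y, within = within, directed = directed, maxgap = maxgap)
  join_assemble(x, y, h$query, h$subject, suffix = suffix)
}

#' @rdname join_overlap_inner
#' @export
join_overlap_intersect <- function(x, y, within = FALSE, directed = FALSE,
                                   maxgap = -1L, suffix = c(".x", ".y")) {
  h <- find_overlap_hits(x, y, within = within, directed = directed, maxgap = maxgap)
  s <- pmax(x$start[h$query], y$start[h$subject])
  e <- pmin(x$end[h$query], y$end[h$subject])
  join_assemble(x, y, h$query, h$subject, start = s, end = e, suffix = suffix)
}

#' @rdname join_overlap_inner
#' @export
join_overlap_left <- function(x, y, within = FALSE, directed = FALSE,
                              maxgap = -1L, suffix = c(".x", ".y")) {
  h <- find_overlap_hits(x, y, within = within, directed = directed, maxgap = maxgap)
  unmatched <- setdiff(seq_len(nrow(x)), h$query)
  q <- c(h$query, unmatched)
  s <- c(h$subject, rep(NA_integer_, length(unmatched)))
  o <- stable_order(q, s)
  join_assemble(x, y, q[o], s[o])
}

join_proximity <- function(x, y, mode, suffix = c(".x", ".y")) {
  h <- find_nearest_hits(x, y, mode = mode)
  join_assemble(x, y, h$query, h$subject, suffix = suffix)
}

#' @rdname join_overlap_inner
#' @export
join_nearest <- function(x, y, suffix = c(".x", ".y")) {
  join_proximity(x, y, "nearest", suffix)
}

#' @rdname join_overlap_inner
#' @export
join_precede <- function(x, y, suffix = c(".x", ".y")) {
  join_proximity(x, y, "precede", suffix)
}

#' @rdname join_overlap_inner
#' @export
join_follow <- function(x, y, suffix = c(".x", ".y")) {
  join_proximity(x, y, "follow", suffix)
}

#' Restrict or partition a table by overlap with another
#'
#' `filter_by_overlaps()` keeps the `x` rows hit at least once by `y`;
#' `filter_by_non_overlaps()` keeps the rest. Each row appears at most once,
#' in its original order, metadata untouched; the two results partition `x`.
#'
#' `group_by_overlaps()` performs an inner overlap join and groups the result
#' by a synthetic `query` column identifying the `y` row (window) each `x`
#' row fell in — combined with [tile_genome()] and `summarise()` this yields
#' windowed statistics.
#'
#' @inheritParams find_overlap_hits
#' @examples
#' gi <- genome_info(c(chr1 = 30))
#' reads <- range_table("chr1", c(2, 12, 14), c(6, 16, 18), score = c(1, 2, 3))
#' tiles <- tile_genome(gi, 10)
#' summarise(group_by_overlaps(reads, tiles), n = n(), mean_score = mean(score))
#' @export
filter_by_overlaps <- function(x, y, maxgap = -1L) {
  h <- find_overlap_hits(x, y, maxgap = maxgap)
  x[sort(unique(h$query)), , drop = FALSE]
}

#' @rdname filter_by_overlaps
#' @export
filter_by_non_overlaps <- function(x, y, maxgap = -1L) {
  h <- find_overlap_hits(x, y, maxgap = maxgap)
  x[setdiff(seq_len(nrow(x)), h$query), , drop = FALSE]
}

#' @rdname filter_by_overlaps
#' @export
group_by_overlaps <- function(x, y, maxgap = -1L) {
  h <- find_overlap_hits(x, y, maxgap = maxgap)
  out <- join_assemble(x, y, h$query, h$subject)
  out$query <- h$subject
  as_grouped(out, "query")
}

#' Fixed-width tiles over a genome
#'
#' Cuts every sequence of a genome into adjacent, non-overlapping windows of
#' `width` bases (the last tile of each sequence is truncated at the
#' sequence end), so the tiles cover each sequence exactly.
#'
#' @param gi A [genome_info()].
#' @param width Positive integer tile width in bases.
#' @return An unstranded `RangeTable` with the genome attached.
#' @examples
#' tile_genome(genome_info(c(chr1 = 25)), 10)   # [1,10] [11,20] [21,25]
#' @export
tile_genome <- function(gi, width) {
  stopifnot(inherits(gi, "GenomeInfo"))
  if (!is_count(width, min = 1L)) {
    rt_stop("tile width must be a single positive integer", "rt_contract_error")
  }
  width <- as.integer(width)
  starts <- lapply(gi$seqlengths, function(L) seq.int(1L, L, by = width))
  n_each <- lengths(starts)
  s <- unlist(starts, use.names = FALSE)
  lens <- rep(unname(gi$seqlengths), n_each)
  merged_table(rep(names(gi$seqlengths), n_each), s,
               pmin(s + width - 1L, lens), "*", gi)
}
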