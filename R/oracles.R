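#' Naive reference oracles
#'
#' Deliberately unoptimized reference implementations — nested loops and
#' per-base arrays, sharing no code with the package's interval engine — used
#' by the differential tests. Agreement between an engine operation and its
#' oracle on random inputs is the package's primary correctness evidence,
#' which is only meaningful because these stay naive; do not "improve" them.
#'
#' * `oracle_hits()` — quadratic scan over all (query, subject) pairs, with
#'   the same `within`/`directed`/`maxgap` semantics as
#'   [find_overlap_hits()], or `mode = "nearest"/"precede"/"follow"` per
#'   [find_nearest_hits()].
#' * `oracle_base_set()` — one logical vector per sequence marking covered
#'   bases (sequence lengths from the attached genome, else `max(end)`).
#' * `oracle_coverage()` — one integer vector per sequence counting covering
#'   rows at each base.
#'
#' @param x,y `RangeTable`s.
#' @param mode Matching algorithm; `"overlap"` returns all pairs.
#' @param within,directed,maxgap As in [find_overlap_hits()].
#' @return `oracle_hits()`: a `RangeHits` data.frame; the others: a named
#'   list of per-base vectors.
#' @name oracles
NULL

#' @rdname oracles
#' @export
oracle_hits <- function(x, y, mode = c("overlap", "nearest", "precede", "follow"),
                        within = FALSE, directed = FALSE, maxgap = -1L) {
  mode <- match.arg(mode)
  maxgap <- as.integer(maxgap)
  q_all <- integer(); s_all <- integer()
  for (i in seq_len(nrow(x))) {
    if (mode == "overlap") {
      for (j in seq_len(nrow(y))) {
        if (x$seqnames[i] != y$seqnames[j]) next
        gap <- max(x$start[i], y$start[j]) - min(x$end[i], y$end[j]) - 1L
        if (gap > maxgap) next
        if (within && !(y$start[j] <= x$start[i] && x$end[i] <= y$end[j])) next
        if (directed && x$strand[i] != y$strand[j]) next
        q_all <- c(q_all, i); s_all <- c(s_all, j)
      }
    } else {
      best_j <- NA_integer_; best_gap <- Inf
      for (j in seq_len(nrow(y))) {
        if (x$seqnames[i] != y$seqnames[j]) next
        if (mode == "precede" && !(y$start[j] > x$end[i])) next
        if (mode == "follow" && !(y$end[j] < x$start[i])) next
        gap <- max(0L, max(x$start[i], y$start[j]) - min(x$end[i], y$end[j]) - 1L)
        if (gap < best_gap) { best_gap <- gap; best_j <- j }
      }
      if (!is.na(best_j)) { q_all <- c(q_all, i); s_all <- c(s_all, best_j) }
    }
  }
  new_hits(q_all, s_all)
}

oracle_seqlens <- function(x) {
  gi <- get_genome_info(x)
  if (!is.null(gi)) return(gi$seqlengths)
  lens <- integer()
  for (i in seq_len(nrow(x))) {
    sq <- x$seqnames[i]
    cur <- if (sq %in% names(lens)) lens[[sq]] else 0L
    lens[sq] <- max(cur, x$end[i])
  }
  lens
}

#' @rdname oracles
#' @export
oracle_base_set <- function(x) {
  lens <- oracle_seqlens(x)
  sets <- lapply(lens, function(L) rep(FALSE, L))
  for (i in seq_len(nrow(x))) {
    if (x$end[i] < x$start[i]) next
    for (b in x$start[i]:x$end[i]) sets[[x$seqnames[i]]][b] <- TRUE
  }
  sets
}

#' @rdname oracles
#' @export
oracle_coverage <- function(x) {
  lens <- oracle_seqlens(x)
  cov <- lapply(lens, function(L) rep(0L, L))
  for (i in seq_len(nrow(x))) {
    if (x$end[i] < x$start[i]) next
    for (b in x$start[i]:x$end[i]) {
      cov[[x$seqnames[i]]][b] <- cov[[x$seqnames[i]]][b] + 1L
    }
  }
  cov
}
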