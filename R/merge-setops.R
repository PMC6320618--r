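# Merging (set-wise) operations: reduce, disjoin, coverage, complement, and
# the range-wise intersect/union/setdiff. These treat each table as a set of
# covered bases per sequence. By default they are insensitive to strand; the
# *_directed variants restrict every operation within strand classes and keep
# the strand in the output. Merged rows carry strand "*" and no metadata
# unless explicitly aggregated (reduce/disjoin are the sanctioned
# metadata-carrying paths). Output ordering is deterministic: seqnames in
# genome order (first appearance if no genome), then start, then end.

# Sorted-sweep run detection. Returns run ids (per sorted position), the
# sorted permutation, and per-run coordinates. Rows whose start lies at most
# gap+1 past the running maximum end join the current run; gap = 0 merges
# abutting ("neighboring") ranges.
sweep_runs <- function(seqnames, start, end, levels) {
  qi <- match(seqnames, levels)
  ord <- stable_order(qi, start, end)
  s <- start[ord]; e <- end[ord]; q <- qi[ord]
  n <- length(s)
  if (n == 0L) {
    return(list(ord = integer(), run = integer(), n_runs = 0L,
                run_seq = character(), run_start = integer(), run_end = integer()))
  }
  cm <- stats::ave(e, q, FUN = cummax)
  new_run <- c(TRUE, q[-1L] != q[-n] | s[-1L] > cm[-n] + 1L)
  run <- cumsum(new_run)
  list(
    ord = ord, run = run, n_runs = max(run),
    run_seq = seqnames[ord][new_run],
    run_start = s[new_run],
    run_end = as.integer(tapply(e, run, max))
  )
}

merged_table <- function(seqnames, start, end, strand, gi, extra = NULL) {
  df <- data.frame(seqnames = as.character(seqnames), start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(start)),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  new_range_table(df, genome_info = gi)
}

# Run an undirected set-wise operation within strand classes.
directed_dispatch <- function(op, x, y = NULL) {
  classes <- c("+", "-", "*")
  parts <- lapply(classes, function(st) {
    xs <- x[x$strand == st, , drop = FALSE]
    res <- if (is.null(y)) op(xs) else op(xs, y[y$strand == st, , drop = FALSE])
    if (nrow(res)) res$strand <- st
    res
  })
  out <- bind_ranges(parts)
  lv <- seq_levels(x)
  out[stable_order(match(out$seqnames, c(lv, setdiff(unique(out$seqnames), lv))),
                   out$start, out$end, match(out$strand, classes)), , drop = FALSE]
}

#' Reduce: merge overlapping and neighboring ranges
#'
#' Collapses every maximal run of overlapping-or-abutting ranges (gap 0, i.e.
#' `end + 1 == start`, counts as touching) into a single row, optionally
#' evaluating aggregation expressions over the source rows of each run and
#' storing the results as metadata. The output is sorted, pairwise disjoint,
#' with gaps of at least 1 between rows; reducing is idempotent. On a grouped
#' table, merging happens within each group and the keys become metadata
#' columns. `reduce_ranges()` ignores strand (merged rows are unstranded);
#' `reduce_ranges_directed()` merges within strand classes and keeps strand.
#'
#' @param x A `RangeTable` (possibly grouped).
#' @param ... Named aggregation expressions, evaluated over the source rows
#'   of each merged run (e.g. `peak = max(score)`).
#' @return A `RangeTable`.
#' @examples
#' rng <- range_table("chr1", c(1, 4, 10), c(5, 8, 12), score = c(3, 8, 5))
#' reduce_ranges(rng, peak = max(score))
#' @export
reduce_ranges <- function(x, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  reduce_impl(x, exprs, parent.frame(), directed = FALSE)
}

#' @rdname reduce_ranges
#' @export
reduce_ranges_directed <- function(x, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  reduce_impl(x, exprs, parent.frame(), directed = TRUE)
}

reduce_impl <- function(x, exprs, env, directed) {
  stopifnot(inherits(x, "RangeTable"))
  if (length(exprs) && (is.null(names(exprs)) || any(names(exprs) == ""))) {
    rt_stop("aggregation expressions must be named", "rt_contract_error")
  }
  keys <- group_keys_of(x)
  lv <- seq_levels(x)
  gi <- get_genome_info(x)
  groups <- group_rows(x)
  if (directed) {
    groups <- unlist(lapply(groups, function(rows) {
      lapply(c("+", "-", "*"), function(st) rows[x$strand[rows] == st])
    }), recursive = FALSE)
  }
  groups <- Filter(length, groups)
  pieces <- lapply(groups, function(rows) {
    sub <- x[rows, , drop = FALSE]
    rn <- sweep_runs(sub$seqnames, sub$start, sub$end, lv)
    members <- split(rows[rn$ord], rn$run)
    extra <- list()
    for (kk in keys) extra[[kk]] <- rep(as.data.frame(x)[[kk]][rows[1L]], rn$n_runs)
    for (nm in names(exprs)) {
      extra[[nm]] <- eval_per_group_scalar(x, exprs[[nm]], members, env, nm)
    }
    st <- if (directed) x$strand[rows[1L]] else "*"
    merged_table(rn$run_seq, rn$run_start, rn$run_end, st, NULL, extra)
  })
  if (!length(pieces)) {
    return(merged_table(character(), integer(), integer(), character(), gi,
                        stats::setNames(rep(list(logical()), length(names(exprs))),
                                        names(exprs))))
  }
  out <- bind_ranges(pieces)
  if (is.null(keys) && !directed) {
    out <- out[stable_order(match(out$seqnames, lv), out$start, out$end), ,
               drop = FALSE]
  }
  set_genome_info(out, gi)
}

#' Disjoin: partition covered bases at every range boundary
#'
#' Splits the union of the input ranges at every distinct start and end
#' coordinate, producing maximal pieces over which the set of covering source
#' rows is constant. Aggregations are evaluated over exactly the rows
#' covering each piece. Pieces are disjoint and their union equals the union
#' of the input; width-0 rows cover no bases and are ignored.
#' `disjoin_ranges_directed()` partitions within strand classes.
#'
#' @inheritParams reduce_ranges
#' @return A `RangeTable`, sorted, one row per piece.
#' @examples
#' disjoin_ranges(range_table("chr1", c(1, 5), c(10, 15)), n_cov = n())
#' @export
disjoin_ranges <- function(x, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  disjoin_impl(x, exprs, parent.frame(), directed = FALSE)
}

#' @rdname disjoin_ranges
#' @export
disjoin_ranges_directed <- function(x, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  disjoin_impl(x, exprs, parent.frame(), directed = TRUE)
}

disjoin_impl <- function(x, exprs, env, directed) {
  stopifnot(inherits(x, "RangeTable"))
  if (length(exprs) && (is.null(names(exprs)) || any(names(exprs) == ""))) {
    rt_stop("aggregation expressions must be named", "rt_contract_error")
  }
  gi <- get_genome_info(x)
  lv <- seq_levels(x)
  strata <- if (directed) c("+", "-", "*") else "*"
  out_seq <- character(); out_s <- integer(); out_e <- integer()
  out_strand <- character(); member_sets <- list()
  for (st in strata) {
    rows_st <- if (directed) which(x$strand == st) else seq_len(nrow(x))
    rows_st <- rows_st[x$end[rows_st] >= x$start[rows_st]]   # width >= 1
    for (sq in lv[lv %in% x$seqnames[rows_st]]) {
      rows <- rows_st[x$seqnames[rows_st] == sq]
      s <- x$start[rows]; e <- x$end[rows]
      bs <- sort(unique(c(s, e + 1L)))
      for (k in seq_len(length(bs) - 1L)) {
        b <- bs[k]
        covering <- rows[s <= b & e >= b]
        if (!length(covering)) next
        out_seq <- c(out_seq, sq)
        out_s <- c(out_s, b)
        out_e <- c(out_e, bs[k + 1L] - 1L)
        out_strand <- c(out_strand, st)
        member_sets[[length(member_sets) + 1L]] <- covering
      }
    }
  }
  extra <- list()
  for (nm in names(exprs)) {
    extra[[nm]] <- if (length(member_sets)) {
      eval_per_group_scalar(x, exprs[[nm]], member_sets, env, nm)
    } else logical()
  }
  out <- merged_table(out_seq, out_s, out_e, out_strand, gi, extra)
  out[stable_order(match(out$seqnames, lv), out$start, out$end,
                   match(out$strand, c("+", "-", "*"))), , drop = FALSE]
}

#' Coverage: per-base depth as constant-score runs
#'
#' Computes, for every base of the genome, how many input ranges cover it,
#' and returns the result as a table of maximal constant-depth runs with the
#' depth in a `score` column — the in-memory form of a bedGraph track.
#' Zero-depth runs are included; when no genome is attached, each sequence
#' extends to its largest covered coordinate. Adjacent runs always differ in
#' score, runs tile each sequence exactly, and the conservation identity
#' `sum(score * width) == sum(width(x))` holds.
#'
#' @param x A `RangeTable`.
#' @return A `RangeTable` with a numeric `score` column.
#' @examples
#' gi <- genome_info(c(chr1 = 10))
#' compute_coverage(range_table("chr1", c(1, 3), c(5, 8), genome_info = gi))
#' @export
compute_coverage <- function(x) {
  stopifnot(inherits(x, "RangeTable"))
  gi <- get_genome_info(x)
  lv <- seq_levels(x)
  out_seq <- character(); out_s <- integer(); out_e <- integer(); out_sc <- integer()
  for (sq in lv) {
    rows <- which(x$seqnames == sq & x$end >= x$start)
    L <- if (!is.null(gi)) gi$seqlengths[[sq]] else
      if (length(rows)) max(x$end[rows]) else 0L
    if (L == 0L) next
    s <- x$start[rows]; e <- x$end[rows]
    pos <- c(1L, s, e + 1L, L + 1L)
    delta <- c(0L, rep(1L, length(s)), rep(-1L, length(e)), 0L)
    agg <- tapply(delta, pos, sum)
    bs <- as.integer(names(agg))
    keep <- bs <= L + 1L           # events at L+1 only close the last run
    depth <- cumsum(as.integer(agg))[keep]
    bs <- bs[keep]
    k <- length(bs) - 1L
    if (k < 1L) next
    run_s <- bs[-length(bs)]
    run_e <- bs[-1L] - 1L
    run_d <- depth[-length(depth)]
    same <- c(FALSE, run_d[-k] == run_d[-1L])   # merge equal-depth neighbours
    grp <- cumsum(!same)
    out_seq <- c(out_seq, rep(sq, max(grp)))
    out_s <- c(out_s, run_s[!same])
    out_e <- c(out_e, as.integer(tapply(run_e, grp, max)))
    out_sc <- c(out_sc, run_d[!same])
  }
  merged_table(out_seq, out_s, out_e, "*", gi, list(score = as.numeric(out_sc)))
}

#' Complement: the uncovered bases of a genome
#'
#' The unary merging operation: returns the sorted, disjoint ranges of every
#' base within `[1, seqlength]` not covered by any input range. Requires an
#' attached genome (sequences of the genome absent from `x` are returned
#' whole).
#'
#' @param x A `RangeTable` with a [genome_info()].
#' @examples
#' gi <- genome_info(c(chr1 = 20))
#' complement_ranges(range_table("chr1", 5, 10, genome_info = gi))
#' @export
complement_ranges <- function(x) {
  gi <- get_genome_info(x)
  if (is.null(gi)) {
    rt_stop("complement_ranges() needs a genome: attach one with set_genome_info()",
            "rt_contract_error")
  }
  red <- reduce_ranges(x)
  out_seq <- character(); out_s <- integer(); out_e <- integer()
  for (sq in names(gi$seqlengths)) {
    L <- gi$seqlengths[[sq]]
    rows <- which(red$seqnames == sq & red$end >= red$start)
    edges_s <- c(1L, red$end[rows] + 1L)
    edges_e <- c(red$start[rows] - 1L, L)
    keep <- edges_s <= edges_e
    out_seq <- c(out_seq, rep(sq, sum(keep)))
    out_s <- c(out_s, edges_s[keep])
    out_e <- c(out_e, edges_e[keep])
  }
  merged_table(out_seq, out_s, out_e, "*", gi)
}

# Reduced runs of a table as parallel vectors, for the binary merge ops.
reduced_runs <- function(x, lv) {
  keep <- x$end >= x$start
  rn <- sweep_runs(x$seqnames[keep], x$start[keep], x$end[keep], lv)
  list(seq = rn$run_seq, s = rn$run_start, e = rn$run_end)
}

merge_levels <- function(x, y) {
  lv <- seq_levels(x)
  c(lv, setdiff(unique(y$seqnames), lv))
}

#' Merging set operations between two range tables
#'
#' Treat `x` and `y` each as a set of covered bases per sequence and return
#' the sorted, disjoint, minimal set of ranges covering the intersection,
#' union or difference of those base sets. Metadata is dropped (merged
#' ranges have no single source row) and the result is unstranded; the
#' `_directed` variants operate within strand classes and keep strand. The
#' genome of `x` (if any) is carried over.
#'
#' Note the contrast with the parallel operators: `x %setdiff% y` subtracts
#' row i of `y` from row i of `x` and insists on a contiguous result, while
#' `setdiff_ranges(x, y)` subtracts the whole base set of `y` from that of
#' `x`, splitting ranges as needed.
#'
#' @param x,y `RangeTable`s.
#' @return An unstranded, metadata-free `RangeTable`.
#' @examples
#' a <- range_table("chr1", c(1, 20), c(10, 30))
#' b <- range_table("chr1", 5, 25)
#' intersect_ranges(a, b)   # [5,10], [20,25]
#' @name merging-ops
NULL

#' @rdname merging-ops
#' @export
intersect_ranges <- function(x, y) {
  lv <- merge_levels(x, y)
  a <- reduced_runs(x, lv); b <- reduced_runs(y, lv)
  out_seq <- character(); out_s <- integer(); out_e <- integer()
  for (sq in lv) {
    ia <- which(a$seq == sq); ib <- which(b$seq == sq)
    i <- 1L; j <- 1L
    while (i <= length(ia) && j <= length(ib)) {
      lo <- max(a$s[ia[i]], b$s[ib[j]])
      hi <- min(a$e[ia[i]], b$e[ib[j]])
      if (lo <= hi) {
        out_seq <- c(out_seq, sq); out_s <- c(out_s, lo); out_e <- c(out_e, hi)
      }
      if (a$e[ia[i]] < b$e[ib[j]]) i <- i + 1L else j <- j + 1L
    }
  }
  merged_table(out_seq, out_s, out_e, "*", get_genome_info(x))
}

#' @rdname merging-ops
#' @export
union_ranges <- function(x, y) {
  lv <- merge_levels(x, y)
  both <- rbind(as.data.frame(x)[CORE_COLS], as.data.frame(y)[CORE_COLS])
  r <- reduced_runs(new_range_table(both, validate = FALSE), lv)
  merged_table(r$seq, r$s, r$e, "*", get_genome_info(x))
}

#' @rdname merging-ops
#' @export
setdiff_ranges <- function(x, y) {
  lv <- merge_levels(x, y)
  a <- reduced_runs(x, lv); b <- reduced_runs(y, lv)
  out_seq <- character(); out_s <- integer(); out_e <- integer()
  for (sq in lv) {
    ia <- which(a$seq == sq); ib <- which(b$seq == sq)
    for (i in ia) {
      cur <- a$s[i]
      for (j in ib) {
        if (b$e[j] < cur || b$s[j] > a$e[i]) next
        if (b$s[j] > cur) {
          out_seq <- c(out_seq, sq); out_s <- c(out_s, cur)
          out_e <- c(out_e, b$s[j] - 1L)
        }
        cur <- max(cur, b$e[j] + 1L)
      }
      if (cur <= a$e[i]) {
        out_seq <- c(out_seq, sq); out_s <- c(out_s, cur); out_e <- c(out_e, a$e[i])
      }
    }
  }
  merged_table(out_seq, out_s, out_e, "*", get_genome_info(x))
}

#' @rdname merging-ops
#' @export
intersect_ranges_directed <- function(x, y) directed_dispatch(intersect_ranges, x, y)

#' @rdname merging-ops
#' @export
union_ranges_directed <- function(x, y) directed_dispatch(union_ranges, x, y)

#' @rdname merging-ops
#' @export
setdiff_ranges_directed <- function(x, y) directed_dispatch(setdiff_ranges, x, y)
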