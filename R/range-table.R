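#' Tidy tables of genomic ranges
#'
#' A `RangeTable` is a data.frame with the fixed columns `seqnames`, `start`,
#' `end` and `strand`, plus any number of metadata columns, one observation
#' per row. Coordinates are 1-based and inclusive, so `width = end - start +
#' 1`; `end = start - 1` encodes a legal width-0 (insertion-point) range.
#' Strand is `"+"`, `"-"` or `"*"` (unstranded). Width is always derived,
#' never stored. An optional [genome_info()] rides along as an attribute and
#' is checked by every verb: no range may extend past its sequence.
#'
#' All grammar verbs except `summarise()` are endomorphic — they return a
#' valid `RangeTable` — so pipelines compose freely.
#'
#' @param seqnames Character vector of sequence (chromosome) names.
#' @param start,end Integer coordinates, 1-based inclusive; `end >= start - 1`.
#' @param strand `"+"`, `"-"` or `"*"`; recycled. Default unstranded.
#' @param ... Metadata columns (named vectors, recycled to the row count).
#' @param genome_info Optional [genome_info()] for integrity checking.
#' @return A `RangeTable`.
#' @examples
#' rng <- range_table(
#'   seqnames = c("chr1", "chr1", "chr2"),
#'   start = c(10, 30, 5), end = c(19, 35, 5),
#'   strand = c("+", "-", "*"), score = c(1.5, 2, 0)
#' )
#' rng
#' ranges_width(rng)
#' @export
range_table <- function(seqnames, start, end, strand = "*", ...,
                        genome_info = NULL) {
  n <- length(start)
  df <- data.frame(
    seqnames = recycle_to(as.character(seqnames), n, "seqnames"),
    start = as.integer(start),
    end = recycle_to(as.integer(end), n, "end"),
    strand = recycle_to(as.character(strand), n, "strand"),
    stringsAsFactors = FALSE
  )
  meta <- list(...)
  if (length(meta)) {
    if (is.null(names(meta)) || any(names(meta) == "")) {
      rt_stop("metadata columns must be named", "rt_contract_error")
    }
    for (nm in names(meta)) df[[nm]] <- recycle_to(meta[[nm]], n, nm)
  }
  new_range_table(df, genome_info = genome_info)
}

CORE_COLS <- c("seqnames", "start", "end", "strand")
RESERVED_COLS <- c(CORE_COLS, "width")

# Low-level constructor: takes a data.frame already holding the core columns.
new_range_table <- function(df, genome_info = NULL, validate = TRUE) {
  rownames(df) <- NULL
  df <- df[, c(CORE_COLS, setdiff(names(df), CORE_COLS)), drop = FALSE]
  structure(df, genome_info = genome_info,
            class = c("RangeTable", "data.frame")) -> out
  if (validate) validate_range_table(out)
  out
}

#' Validate RangeTable invariants
#'
#' Checks coordinate sanity (`start >= 1`, `end >= start - 1`), strand codes,
#' metadata-name uniqueness, and — when a genome is attached — that every
#' seqname is known and every `end` is within its sequence length. Errors
#' name the first offending row.
#'
#' @param x A `RangeTable`.
#' @return `x`, invisibly.
#' @export
validate_range_table <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(CORE_COLS %in% names(x))) {
    rt_stop("a RangeTable needs seqnames, start, end and strand columns",
            "rt_contract_error")
  }
  meta <- setdiff(names(x), CORE_COLS)
  if ("width" %in% meta) {
    rt_stop("'width' is derived from start/end and cannot be a stored column",
            "rt_contract_error")
  }
  if (anyDuplicated(names(x))) {
    rt_stop(sprintf("duplicate column name '%s'", names(x)[duplicated(names(x))][1L]),
            "rt_contract_error")
  }
  s <- x$start; e <- x$end
  if (anyNA(s) || anyNA(e)) {
    rt_stop(sprintf("row %d: missing coordinate", which(is.na(s) | is.na(e))[1L]),
            "rt_integrity_error")
  }
  bad <- which(s < 1L)
  if (length(bad)) {
    rt_stop(sprintf("row %d: start %d is below coordinate 1", bad[1L], s[bad[1L]]),
            "rt_integrity_error")
  }
  bad <- which(e < s - 1L)
  if (length(bad)) {
    rt_stop(sprintf("row %d: end %d < start %d - 1", bad[1L], e[bad[1L]], s[bad[1L]]),
            "rt_integrity_error")
  }
  bad <- which(!x$strand %in% c("+", "-", "*"))
  if (length(bad)) {
    rt_stop(sprintf("row %d: strand must be '+', '-' or '*' (got '%s')",
                    bad[1L], x$strand[bad[1L]]), "rt_integrity_error")
  }
  gi <- attr(x, "genome_info", exact = TRUE)
  if (!is.null(gi)) {
    lens <- gi$seqlengths
    unknown <- which(!x$seqnames %in% names(lens))
    if (length(unknown)) {
      rt_stop(sprintf("row %d: seqname '%s' is not in the genome",
                      unknown[1L], x$seqnames[unknown[1L]]), "rt_integrity_error")
    }
    over <- which(e > unname(lens[x$seqnames]))
    if (length(over)) {
      rt_stop(sprintf("row %d: end %d exceeds length of %s (%d)",
                      over[1L], e[over[1L]], x$seqnames[over[1L]],
                      lens[[x$seqnames[over[1L]]]]), "rt_integrity_error")
    }
  }
  invisible(x)
}

#' Coerce a data.frame to a RangeTable
#'
#' Accepts a data.frame with `seqnames`/`start`/`end` (and optionally
#' `strand`, `width`) columns. A `width` column, if present, is consumed to
#' derive `end` when `end` is absent, and dropped otherwise.
#'
#' @param df A data.frame.
#' @param genome_info Optional [genome_info()].
#' @export
as_range_table <- function(df, genome_info = NULL) {
  df <- as.data.frame(df)
  if (!"end" %in% names(df) && all(c("start", "width") %in% names(df))) {
    df$end <- as.integer(df$start) + as.integer(df$width) - 1L
  }
  df$width <- NULL
  if (!"strand" %in% names(df)) df$strand <- "*"
  df$seqnames <- as.character(df$seqnames)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  new_range_table(df, genome_info = genome_info)
}

#' @rdname range_table
#' @param x A `RangeTable`.
#' @export
ranges_width <- function(x) x$end - x$start + 1L

#' Get or set the genome attached to a range table
#' @param x A `RangeTable`.
#' @param gi A [genome_info()] object, or `NULL` to detach.
#' @export
get_genome_info <- function(x) attr(x, "genome_info", exact = TRUE)

#' @rdname get_genome_info
#' @export
set_genome_info <- function(x, gi) {
  stopifnot(inherits(x, "RangeTable"), is.null(gi) || inherits(gi, "GenomeInfo"))
  attr(x, "genome_info") <- gi
  validate_range_table(x)
  x
}

# Sequence ordering used by merging operations: genome order when known,
# first appearance otherwise.
seq_levels <- function(x) {
  gi <- get_genome_info(x)
  if (!is.null(gi)) names(gi$seqlengths) else unique(x$seqnames)
}

# Metadata columns as a plain data.frame (possibly 0-column).
meta_cols <- function(x) {
  as.data.frame(x)[, setdiff(names(x), CORE_COLS), drop = FALSE]
}

#' @export
print.RangeTable <- function(x, n = 8L, ...) {
  gi <- get_genome_info(x)
  anchor <- attr(x, "anchor", exact = TRUE)
  groups <- attr(x, "group_keys", exact = TRUE)
  cat(sprintf("RangeTable with %d range(s) and %d metadata column(s)\n",
              nrow(x), ncol(x) - 4L))
  if (!is.null(anchor)) cat(sprintf("  anchored at: %s\n", anchor))
  if (!is.null(groups)) cat(sprintf("  groups: %s\n", paste(groups, collapse = ", ")))
  df <- as.data.frame(x)
  df <- cbind(df[CORE_COLS], width = ranges_width(x),
              df[setdiff(names(df), CORE_COLS)])
  print(utils::head(df, n))
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  if (!is.null(gi)) {
    cat(sprintf("genome: %d sequence(s)%s\n", length(gi$seqlengths),
                if (is.null(gi$build)) "" else paste0(" [", gi$build, "]")))
  }
  invisible(x)
}

#' @export
`[.RangeTable` <- function(x, i, j, drop = FALSE) {
  out <- `[.data.frame`(as.data.frame(x), i, j, drop = drop)
  if (!is.data.frame(out) || !all(CORE_COLS %in% names(out))) return(out)
  new_range_table(out, genome_info = get_genome_info(x), validate = FALSE)
}

#' @export
as.data.frame.RangeTable <- function(x, ...) {
  attr(x, "genome_info") <- NULL
  attr(x, "anchor") <- NULL
  attr(x, "group_keys") <- NULL
  class(x) <- "data.frame"
  x
}

#' Concatenate range tables row-wise
#'
#' Metadata columns are unioned; values absent on one side become `NA`. The
#' genome of the first table carrying one is kept (all attached genomes must
#' agree).
#'
#' @param ... `RangeTable`s.
#' @export
bind_ranges <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) && !is.data.frame(tabs[[1L]])) {
    tabs <- tabs[[1L]]
  }
  stopifnot(length(tabs) > 0L)
  gis <- Filter(Negate(is.null), lapply(tabs, get_genome_info))
  if (length(gis) > 1L) {
    for (g in gis[-1L]) {
      if (!identical(g$seqlengths, gis[[1L]]$seqlengths)) {
        rt_stop("cannot bind tables from different genomes", "rt_contract_error")
      }
    }
  }
  all_cols <- unique(unlist(lapply(tabs, names)))
  dfs <- lapply(tabs, function(t) {
    df <- as.data.frame(t)
    for (nm in setdiff(all_cols, names(df))) df[[nm]] <- NA
    df[, all_cols, drop = FALSE]
  })
  new_range_table(do.call(rbind, dfs),
                  genome_info = if (length(gis)) gis[[1L]] else NULL)
}
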