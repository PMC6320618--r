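#' Genome bookkeeping: per-sequence lengths and a build tag
#'
#' A `GenomeInfo` records the length in bases of every sequence (chromosome)
#' in a genome, plus an optional build label (e.g. `"hg19"`). Attaching one to
#' a [range_table()] turns on integrity checks (every range must lie within
#' its sequence) and enables [complement_ranges()], [compute_coverage()]
#' zero-runs and [tile_genome()].
#'
#' @param seqlengths Named integer vector of sequence lengths (all positive,
#'   names unique), or a two-column data.frame (name, length).
#' @param build Optional genome build label.
#' @return An object of class `GenomeInfo`.
#' @examples
#' gi <- genome_info(c(chr1 = 1000, chr2 = 500), build = "toy1")
#' seq_lengths(gi)
#' @export
genome_info <- function(seqlengths, build = NULL) {
  if (is.data.frame(seqlengths)) {
    stopifnot(ncol(seqlengths) >= 2L)
    nm <- as.character(seqlengths[[1L]])
    seqlengths <- stats::setNames(seqlengths[[2L]], nm)
  }
  lens <- as.integer(seqlengths)
  nm <- names(seqlengths)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    rt_stop("seqlengths must be a named vector", "rt_contract_error")
  }
  if (anyDuplicated(nm)) {
    rt_stop(sprintf("duplicate seqname in genome: '%s'", nm[duplicated(nm)][1L]),
            "rt_parse_error")
  }
  if (anyNA(lens) || any(lens < 1L)) {
    rt_stop("all sequence lengths must be positive integers", "rt_parse_error")
  }
  if (!is.null(build) && !is_string(build)) {
    rt_stop("build must be a single string", "rt_contract_error")
  }
  structure(list(seqlengths = stats::setNames(lens, nm), build = build),
            class = "GenomeInfo")
}

#' @rdname genome_info
#' @param x A `GenomeInfo` or a range table carrying one.
#' @export
seq_lengths <- function(x) {
  if (inherits(x, "GenomeInfo")) return(x$seqlengths)
  gi <- get_genome_info(x)
  if (is.null(gi)) NULL else gi$seqlengths
}

#' @rdname genome_info
#' @export
genome_build <- function(x) {
  if (inherits(x, "GenomeInfo")) return(x$build)
  gi <- get_genome_info(x)
  if (is.null(gi)) NULL else gi$build
}

#' @export
print.GenomeInfo <- function(x, ...) {
  cat(sprintf("GenomeInfo: %d sequence(s)%s\n", length(x$seqlengths),
              if (is.null(x$build)) "" else paste0(", build ", x$build)))
  print(x$seqlengths)
  invisible(x)
}

#' Full-sequence ranges of a genome
#'
#' Returns one range per sequence spanning `[1, seqlength]` — useful as an
#' `overlap_filter` when reading files restricted to particular chromosomes.
#'
#' @param gi A [genome_info()] object.
#' @param seqnames Optional subset of sequence names to return.
#' @return A `RangeTable` with one row per sequence.
#' @examples
#' get_genome_range(genome_info(c(chr10 = 135534747)))
#' @export
get_genome_range <- function(gi, seqnames = NULL) {
  stopifnot(inherits(gi, "GenomeInfo"))
  lens <- gi$seqlengths
  if (!is.null(seqnames)) {
    missing <- setdiff(seqnames, names(lens))
    if (length(missing)) {
      rt_stop(sprintf("unknown seqname '%s' in genome", missing[1L]), "rt_name_error")
    }
    lens <- lens[seqnames]
  }
  range_table(seqnames = names(lens), start = rep(1L, length(lens)),
              end = unname(lens), genome_info = gi)
}
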