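#' Read and write BED, bedGraph, GFF3 and chrom.sizes files
#'
#' All readers return a `RangeTable` in the package's internal convention of
#' 1-based inclusive coordinates; all coordinate-convention conversion
#' happens here and only here.
#'
#' * **BED** is 0-based half-open: a record `chrom 0 10` becomes `[1, 10]`,
#'   and `chrom 5 5` a width-0 range at start 6. Optional columns 4-6 map to
#'   `name`, `score` (parsed numerically, not clamped to 0-1000) and
#'   `strand` (`"."` reads as unstranded). [write_bed()] always emits six
#'   tab-separated columns (placeholders `"."`/`0` for missing name/score),
#'   newline-terminated, no trailing whitespace, so files round-trip
#'   byte-identically; metadata beyond name/score triggers a lossy-write
#'   warning (an error with `strict = TRUE`).
#' * **bedGraph** is BED-like with a numeric `dataValue` fourth column,
#'   mapped to `score`. Writing requires disjoint ranges per sequence
#'   (coverage-run semantics) and is the on-disk form of
#'   [compute_coverage()] output.
#' * **GFF3** is already 1-based inclusive, so no shift is applied;
#'   `source`, `type`, `score`, `phase` and the parsed `attributes`
#'   key-values become metadata columns. Attribute order is normalized on
#'   write, so GFF3 round-trips are semantic, not byte-exact.
#' * **chrom.sizes** is a two-column name/length TSV, read into a
#'   [genome_info()].
#'
#' `track`/`browser` header lines are skipped with a warning and `#` comment
#' lines silently; tabs or runs of spaces both separate fields on read, tabs
#' only on write. When `genome_info` is supplied, records on unknown
#' sequences are an integrity error; when `overlap_filter` is supplied, only
#' records overlapping it are materialized in the returned table.
#'
#' @param path File path.
#' @param genome_info Optional [genome_info()] to attach and check against.
#' @param overlap_filter Optional `RangeTable`; keep only overlapping records.
#' @param x A `RangeTable` to write.
#' @param strict For [write_bed()]: error instead of warn on lossy writes.
#' @return Readers return a `RangeTable` (or [genome_info()]); writers return
#'   `path` invisibly.
#' @name ranges-io
NULL

io_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  hdr <- grepl("^(track|browser)\\b", lines)
  if (any(hdr)) {
    warning(sprintf("skipped %d track/browser header line(s) in %s",
                    sum(hdr), path))
    keep <- keep & !hdr
  }
  list(lines = lines[keep], lineno = which(keep))
}

field_matrix <- function(path, min_fields, sep = "[\t ]+") {
  got <- io_lines(path)
  fields <- strsplit(got$lines, sep)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad)) {
    rt_stop(sprintf("%s line %d: expected at least %d fields, found %d",
                    path, got$lineno[bad[1L]], min_fields, nf[bad[1L]]),
            "rt_parse_error")
  }
  list(fields = fields, lineno = got$lineno)
}

parse_int <- function(v, path, lineno, what) {
  out <- suppressWarnings(as.integer(v))
  bad <- which(is.na(out) & !is.na(v))
  if (length(bad)) {
    rt_stop(sprintf("%s line %d: %s '%s' is not an integer",
                    path, lineno[bad[1L]], what, v[bad[1L]]), "rt_parse_error")
  }
  out
}

finish_read <- function(df, genome_info, overlap_filter) {
  out <- new_range_table(df, genome_info = genome_info)
  if (!is.null(overlap_filter)) out <- filter_by_overlaps(out, overlap_filter)
  out
}

#' @rdname ranges-io
#' @export
read_bed <- function(path, genome_info = NULL, overlap_filter = NULL) {
  fm <- field_matrix(path, 3L)
  if (!length(fm$fields)) {
    return(finish_read(data.frame(seqnames = character(), start = integer(),
                                  end = integer(), strand = character()),
                       genome_info, overlap_filter))
  }
  f <- function(k) vapply(fm$fields, function(x) if (length(x) >= k) x[[k]] else NA_character_,
                          character(1L))
  s0 <- parse_int(f(2L), path, fm$lineno, "chromStart")
  e0 <- parse_int(f(3L), path, fm$lineno, "chromEnd")
  bad <- which(e0 < s0)
  if (length(bad)) {
    rt_stop(sprintf("%s line %d: chromEnd %d < chromStart %d",
                    path, fm$lineno[bad[1L]], e0[bad[1L]], s0[bad[1L]]),
            "rt_parse_error")
  }
  df <- data.frame(seqnames = f(1L), start = s0 + 1L, end = e0,
                   strand = "*", stringsAsFactors = FALSE)
  nf <- max(lengths(fm$fields))
  if (nf >= 4L) df$name <- f(4L)
  if (nf >= 5L) df$score <- as.numeric(f(5L))
  if (nf >= 6L) {
    st <- f(6L)
    df$strand <- ifelse(st == ".", "*", st)
  }
  finish_read(df, genome_info, overlap_filter)
}

# Deterministic numeric formatting shared by the writers: plain decimal
# notation, no padding, 15 significant digits.
fmt_num <- function(v) {
  out <- vapply(v, function(z) format(z, scientific = FALSE, trim = TRUE,
                                      digits = 15L), character(1L))
  out[is.na(v)] <- "."
  out
}

write_tsv_lines <- function(cols, path) {
  lines <- do.call(paste, c(cols, list(sep = "\t")))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @rdname ranges-io
#' @export
write_bed <- function(x, path, strict = FALSE) {
  stopifnot(inherits(x, "RangeTable"))
  extra <- setdiff(names(meta_cols(x)), c("name", "score"))
  if (length(extra)) {
    msg <- sprintf("BED6 cannot represent metadata column(s): %s",
                   paste(extra, collapse = ", "))
    if (strict) rt_stop(msg, "rt_contract_error") else warning(msg)
  }
  nm <- if ("name" %in% names(x)) as.character(x$name) else rep(".", nrow(x))
  sc <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  write_tsv_lines(list(x$seqnames, x$start - 1L, x$end, nm, fmt_num(sc),
                       ifelse(x$strand == "*", ".", x$strand)), path)
}

#' @rdname ranges-io
#' @export
read_bedgraph <- function(path, genome_info = NULL, overlap_filter = NULL) {
  fm <- field_matrix(path, 4L)
  f <- function(k) vapply(fm$fields, `[[`, character(1L), k)
  if (!length(fm$fields)) {
    return(finish_read(data.frame(seqnames = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  score = numeric()),
                       genome_info, overlap_filter))
  }
  s0 <- parse_int(f(2L), path, fm$lineno, "chromStart")
  e0 <- parse_int(f(3L), path, fm$lineno, "chromEnd")
  bad <- which(e0 < s0)
  if (length(bad)) {
    rt_stop(sprintf("%s line %d: chromEnd %d < chromStart %d",
                    path, fm$lineno[bad[1L]], e0[bad[1L]], s0[bad[1L]]),
            "rt_parse_error")
  }
  df <- data.frame(seqnames = f(1L), start = s0 + 1L, end = e0, strand = "*",
                   score = as.numeric(f(4L)), stringsAsFactors = FALSE)
  finish_read(df, genome_info, overlap_filter)
}

#' @rdname ranges-io
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(inherits(x, "RangeTable"))
  if (!"score" %in% names(x)) {
    rt_stop("bedGraph needs a numeric 'score' column", "rt_contract_error")
  }
  o <- stable_order(x$seqnames, x$start)
  s <- x$start[o]; e <- x$end[o]; sq <- x$seqnames[o]
  n <- length(s)
  if (n > 1L) {
    clash <- which(sq[-1L] == sq[-n] & s[-1L] <= e[-n])
    if (length(clash)) {
      rt_stop("bedGraph runs must be disjoint within each sequence",
              "rt_contract_error")
    }
  }
  write_tsv_lines(list(x$seqnames, x$start - 1L, x$end, fmt_num(x$score)), path)
}

# GFF3 ----------------------------------------------------------------------

GFF_FIXED <- c("source", "type", "score", "phase")

parse_gff_attributes <- function(attr_strings, path, lineno) {
  parsed <- vector("list", length(attr_strings))
  for (i in seq_along(attr_strings)) {
    a <- attr_strings[[i]]
    if (a == "." || a == "") { parsed[[i]] <- list(); next }
    pairs <- strsplit(a, ";", fixed = TRUE)[[1L]]
    pairs <- pairs[nzchar(pairs)]
    kv <- regmatches(pairs, regexec("^([^=]+)=(.*)$", pairs))
    bad <- which(lengths(kv) != 3L)
    if (length(bad)) {
      rt_stop(sprintf("%s line %d: malformed attribute '%s'",
                      path, lineno[i], pairs[bad[1L]]), "rt_parse_error")
    }
    parsed[[i]] <- stats::setNames(
      lapply(kv, `[[`, 3L), trimws(vapply(kv, `[[`, character(1L), 2L)))
  }
  parsed
}

#' @rdname ranges-io
#' @export
read_gff <- function(path, genome_info = NULL, overlap_filter = NULL) {
  # GFF3 columns are tab-separated only: attribute values may contain spaces.
  fm <- field_matrix(path, 9L, sep = "\t")
  if (!length(fm$fields)) {
    return(finish_read(data.frame(seqnames = character(), start = integer(),
                                  end = integer(), strand = character()),
                       genome_info, overlap_filter))
  }
  f <- function(k) vapply(fm$fields, `[[`, character(1L), k)
  st <- f(7L)
  df <- data.frame(
    seqnames = f(1L),
    start = parse_int(f(4L), path, fm$lineno, "start"),
    end = parse_int(f(5L), path, fm$lineno, "end"),
    strand = ifelse(st == ".", "*", st),
    source = f(2L), type = f(3L),
    score = suppressWarnings(as.numeric(ifelse(f(6L) == ".", NA, f(6L)))),
    phase = suppressWarnings(as.integer(ifelse(f(8L) == ".", NA, f(8L)))),
    stringsAsFactors = FALSE
  )
  attrs <- parse_gff_attributes(f(9L), path, fm$lineno)
  keys <- unique(unlist(lapply(attrs, names)))
  for (k in keys) {
    df[[k]] <- vapply(attrs, function(a) a[[k]] %||% NA_character_, character(1L))
  }
  finish_read(df, genome_info, overlap_filter)
}

#' @rdname ranges-io
#' @export
write_gff <- function(x, path) {
  stopifnot(inherits(x, "RangeTable"))
  meta <- meta_cols(x)
  src <- if ("source" %in% names(meta)) as.character(meta$source) else rep(".", nrow(x))
  typ <- if ("type" %in% names(meta)) as.character(meta$type) else rep("feature", nrow(x))
  sc <- if ("score" %in% names(meta)) fmt_num(meta$score) else rep(".", nrow(x))
  ph <- if ("phase" %in% names(meta)) fmt_num(meta$phase) else rep(".", nrow(x))
  attr_cols <- sort(setdiff(names(meta), GFF_FIXED))   # normalized order
  attrs <- rep("", nrow(x))
  for (k in attr_cols) {
    v <- as.character(meta[[k]])
    piece <- ifelse(is.na(v), "", paste0(k, "=", v))
    attrs <- ifelse(nzchar(piece),
                    ifelse(nzchar(attrs), paste(attrs, piece, sep = ";"), piece),
                    attrs)
  }
  attrs[!nzchar(attrs)] <- "."
  lines <- paste(x$seqnames, src, typ, x$start, x$end, sc,
                 ifelse(x$strand == "*", ".", x$strand), ph, attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path, sep = "\n")
  invisible(path)
}

#' @rdname ranges-io
#' @param build Optional genome build label for [read_genome_info()].
#' @export
read_genome_info <- function(path, build = NULL) {
  fm <- field_matrix(path, 2L)
  f <- function(k) vapply(fm$fields, `[[`, character(1L), k)
  if (!length(fm$fields)) rt_stop(sprintf("%s: empty chrom.sizes file", path),
                                  "rt_parse_error")
  lens <- parse_int(f(2L), path, fm$lineno, "length")
  if (any(lens < 1L)) {
    rt_stop(sprintf("%s line %d: non-positive sequence length",
                    path, fm$lineno[which(lens < 1L)[1L]]), "rt_parse_error")
  }
  genome_info(stats::setNames(lens, f(1L)), build = build)
}

#' @rdname ranges-io
#' @param gi A [genome_info()] to serialize.
#' @export
write_genome_info <- function(gi, path) {
  stopifnot(inherits(gi, "GenomeInfo"))
  write_tsv_lines(list(names(gi$seqlengths), unname(gi$seqlengths)), path)
}
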