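#' Seeded synthetic range data
#'
#' `range_sim_spec()` freezes every parameter of a simulation — seed, range
#' count, genome, width distribution, strand frequencies and metadata
#' generators — so that `simulate_ranges(spec)` is fully reproducible: the
#' same spec always yields the identical table (the RNG state of the session
#' is saved and restored around the draw).
#'
#' The defaults describe a desk-scale caricature of feature annotation data:
#' a two-chromosome toy genome, widths uniform on a small window, both
#' strands common with a minority of unstranded rows, and a uniform
#' real-valued `score`. Available metadata generators:
#'
#' * `"score"` — numeric, uniform on \[0, 100\], rounded to 3 decimals;
#' * `"id"` — categorical labels `f01`...`f10`;
#' * `"variant"` — single-nucleotide `REF`/`ALT` pairs drawn uniformly from
#'   the 12 ordered pairs of distinct bases (so transitions occur at the
#'   1/3 rate expected under uniformity).
#'
#' @param seed Integer RNG seed.
#' @param n Number of ranges.
#' @param genome A [genome_info()]; ranges are placed uniformly, sequences
#'   weighted by length, and always lie within their sequence.
#' @param width_range Integer `c(min, max)` of uniform widths (min >= 1).
#' @param strand_probs Probabilities for `+`, `-`, `*` (in that order).
#' @param metadata Character subset of `c("score", "id", "variant")`.
#' @return `range_sim_spec()` returns a spec object; `simulate_ranges()` a
#'   `RangeTable` with the genome attached.
#' @examples
#' spec <- range_sim_spec(seed = 1, n = 5)
#' identical(simulate_ranges(spec), simulate_ranges(spec))
#' @export
range_sim_spec <- function(seed, n,
                           genome = genome_info(c(chrA = 10000L, chrB = 8000L),
                                                build = "toy1"),
                           width_range = c(1L, 50L),
                           strand_probs = c(0.45, 0.45, 0.10),
                           metadata = "score") {
  stopifnot(is_count(seed), is_count(n), inherits(genome, "GenomeInfo"),
            length(width_range) == 2L, all(metadata %in% c("score", "id", "variant")))
  width_range <- as.integer(width_range)
  if (width_range[1L] < 1L || width_range[2L] < width_range[1L]) {
    rt_stop("width_range must satisfy 1 <= min <= max", "rt_spec_error")
  }
  if (width_range[2L] > min(genome$seqlengths)) {
    rt_stop("maximum width exceeds the shortest sequence", "rt_spec_error")
  }
  structure(list(seed = as.integer(seed), n = as.integer(n), genome = genome,
                 width_range = width_range,
                 strand_probs = strand_probs / sum(strand_probs),
                 metadata = metadata),
            class = "RangeSimSpec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' @rdname range_sim_spec
#' @param spec A `RangeSimSpec`.
#' @export
simulate_ranges <- function(spec) {
  stopifnot(inherits(spec, "RangeSimSpec"))
  with_seed(spec$seed, {
    n <- spec$n
    lens <- spec$genome$seqlengths
    sq <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
    w <- sample(seq.int(spec$width_range[1L], spec$width_range[2L]), n,
                replace = TRUE)
    # keep every range inside its sequence
    s <- 1L + as.integer(floor(stats::runif(n) * (unname(lens[sq]) - w + 1L)))
    st <- sample(c("+", "-", "*"), n, replace = TRUE, prob = spec$strand_probs)
    df <- data.frame(seqnames = sq, start = s, end = s + w - 1L, strand = st,
                     stringsAsFactors = FALSE)
    if ("score" %in% spec$metadata) df$score <- round(stats::runif(n, 0, 100), 3L)
    if ("id" %in% spec$metadata) {
      df$id <- sample(sprintf("f%02d", 1:10), n, replace = TRUE)
    }
    if ("variant" %in% spec$metadata) {
      bases <- c("A", "C", "G", "T")
      df$REF <- sample(bases, n, replace = TRUE)
      df$ALT <- vapply(df$REF, function(r) sample(setdiff(bases, r), 1L),
                       character(1L))
    }
    new_range_table(df, genome_info = spec$genome)
  })
}

#' Synthetic coverage track with a planted peak
#'
#' Emulates a normalized ChIP-seq coverage signal over one chromosome as
#' adjacent constant-score runs tiling the sequence exactly (the in-memory
#' equivalent of a bedGraph file). Background run scores are integers drawn
#' uniformly below `peak_height`, some of them above the conventional island
#' threshold of 8 so the track contains several coverage islands; one run of
#' `peak_width` bases is planted at a known position with score
#' `peak_height`, strictly the track maximum. The planted truth is recorded
#' in the `"planted_peak"` attribute (also returned by `planted_peak()`).
#'
#' What this emulates — piecewise-constant depth, islands, one dominant
#' summit — is enough to exercise peak-calling logic; it does not model read
#' sampling noise, replicate variability, or mappability artifacts.
#'
#' @param seed Integer RNG seed.
#' @param genome A single-sequence [genome_info()].
#' @param n_runs Approximate number of constant runs in the track.
#' @param peak_height Score of the planted peak (must exceed every
#'   background score; background is capped at `peak_height - 2`).
#' @param peak_width Width in bases of the planted peak run.
#' @return A `RangeTable` with a `score` column tiling the sequence.
#' @examples
#' trk <- simulate_coverage_track(seed = 7)
#' planted_peak(trk)
#' @export
simulate_coverage_track <- function(seed,
                                    genome = genome_info(c(chr10 = 100000L),
                                                         build = "toy1"),
                                    n_runs = 200L, peak_height = 30L,
                                    peak_width = 1500L) {
  stopifnot(inherits(genome, "GenomeInfo"), length(genome$seqlengths) == 1L,
            is_count(seed), is_count(n_runs, 2L), is_count(peak_height, 10L),
            is_count(peak_width, 1L))
  L <- unname(genome$seqlengths[1L])
  sq <- names(genome$seqlengths)
  with_seed(seed, {
    cuts <- sort(sample(seq_len(L - 1L), n_runs - 1L))
    s <- c(1L, cuts + 1L)
    e <- c(cuts, L)
    score <- sample(0:(peak_height - 2L), length(s), replace = TRUE)
    # plant the peak run over an interior window of the track
    ps <- as.integer(floor(stats::runif(1L, L * 0.25, L * 0.65)))
    pe <- min(ps + peak_width - 1L, L)
    keep <- e < ps | s > pe
    df <- data.frame(seqnames = sq, start = c(s[keep], ps), end = c(e[keep], pe),
                     strand = "*", score = as.numeric(c(score[keep], peak_height)),
                     stringsAsFactors = FALSE)
    # truncate background runs cut by the peak so the runs tile exactly
    df2 <- data.frame(seqnames = sq,
                      start = s[!keep & s < ps], end = rep(ps - 1L, sum(!keep & s < ps)),
                      strand = "*", score = as.numeric(score[!keep & s < ps]))
    df3 <- data.frame(seqnames = sq,
                      start = rep(pe + 1L, sum(!keep & e > pe)), end = e[!keep & e > pe],
                      strand = "*", score = as.numeric(score[!keep & e > pe]))
    out <- rbind(df, df2, df3)
    out <- out[order(out$start), , drop = FALSE]
    trk <- new_range_table(out, genome_info = genome)
    attr(trk, "planted_peak") <- list(start = ps, end = pe,
                                      height = as.numeric(peak_height))
    trk
  })
}

#' @rdname simulate_coverage_track
#' @param x A track made by `simulate_coverage_track()`.
#' @export
planted_peak <- function(x) attr(x, "planted_peak", exact = TRUE)

#' Synthetic variant table with planted transition/transversion counts
#'
#' Builds a SNP/indel table like the metadata of a genotyping array: each row
#' has `REF`/`ALT` alleles. Per chromosome the exact numbers of transitions
#' (purine-purine or pyrimidine-pyrimidine substitutions) and transversions
#' are planted, so the per-chromosome Ti/Tv ratio is known by construction;
#' a few indel rows (multi-base `REF`) and mitochondrial (`chrM`) rows are
#' added as filter fodder.
#'
#' @param seed Integer RNG seed.
#' @param counts Named list: for each chromosome, `c(ti, tv)` planted counts.
#' @param n_indels,n_chrM Rows to add that a QC pipeline should discard.
#' @return A `RangeTable` with `REF`, `ALT` metadata and a genome covering
#'   the named chromosomes plus `chrM`.
#' @examples
#' v <- simulate_variants(1, counts = list(chr1 = c(4, 2)))
#' table(v$seqnames)
#' @export
simulate_variants <- function(seed,
                              counts = list(chr1 = c(8L, 4L), chr2 = c(9L, 3L)),
                              n_indels = 3L, n_chrM = 2L) {
  transitions <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  transversions <- list(c("A", "C"), c("C", "A"), c("A", "T"), c("T", "A"),
                        c("G", "C"), c("C", "G"), c("G", "T"), c("T", "G"))
  with_seed(seed, {
    rows <- list()
    for (sq in names(counts)) {
      ti <- counts[[sq]][1L]; tv <- counts[[sq]][2L]
      pairs <- c(sample(transitions, ti, replace = TRUE),
                 sample(transversions, tv, replace = TRUE))
      pos <- sort(sample(seq_len(90000L), ti + tv))
      rows[[sq]] <- data.frame(
        seqnames = sq, start = pos, end = pos, strand = "*",
        REF = vapply(pairs, `[[`, character(1L), 1L),
        ALT = vapply(pairs, `[[`, character(1L), 2L),
        stringsAsFactors = FALSE)
    }
    if (n_indels > 0L) {
      sq <- sample(names(counts), n_indels, replace = TRUE)
      pos <- sample(seq_len(90000L), n_indels)
      rows$indels <- data.frame(
        seqnames = sq, start = pos, end = pos + 1L, strand = "*",
        REF = "AT", ALT = "A", stringsAsFactors = FALSE)
    }
    if (n_chrM > 0L) {
      pos <- sample(seq_len(16000L), n_chrM)
      rows$chrM <- data.frame(
        seqnames = "chrM", start = pos, end = pos, strand = "*",
        REF = "A", ALT = "G", stringsAsFactors = FALSE)
    }
    gi <- genome_info(stats::setNames(
      c(rep(100000L, length(counts)), 16571L), c(names(counts), "chrM")))
    out <- do.call(rbind, rows)
    out <- out[stable_order(match(out$seqnames, names(gi$seqlengths)), out$start), ]
    new_range_table(out, genome_info = gi)
  })
}
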