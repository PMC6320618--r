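#' Shift ranges without changing their width
#'
#' Moves both coordinates of every range by `amount` bases. Shifting is
#' unanchored, so the direction is part of the function name: `left`/`right`
#' are purely spatial, while `upstream`/`downstream` resolve per row by
#' strand (upstream = left on the plus strand, right on the minus strand;
#' downstream is the mirror image; unstranded rows count as plus). A shift
#' that would push a range below coordinate 1, or past the attached genome's
#' sequence length, raises an integrity error rather than clipping.
#'
#' @param x A `RangeTable`.
#' @param amount Non-negative integer number of bases.
#' @return A `RangeTable` of identical widths.
#' @examples
#' shift_right(range_table("chr1", 2, 5), 3)  # [5, 8]
#' @name shifting
NULL

shift_impl <- function(x, amount, left_on_plus, strand_aware) {
  stopifnot(inherits(x, "RangeTable"))
  if (!is_count(amount)) {
    rt_stop("shift amount must be a single non-negative integer", "rt_contract_error")
  }
  amount <- as.integer(amount)
  going_left <- rep(left_on_plus, nrow(x))
  if (strand_aware) going_left <- xor(going_left, x$strand == "-")
  delta <- ifelse(going_left, -amount, amount)
  df <- as.data.frame(x)
  df$start <- df$start + delta
  df$end <- df$end + delta
  restore_groups(new_range_table(df, genome_info = get_genome_info(x)), x)
}

#' @rdname shifting
#' @export
shift_left <- function(x, amount) shift_impl(x, amount, TRUE, FALSE)

#' @rdname shifting
#' @export
shift_right <- function(x, amount) shift_impl(x, amount, FALSE, FALSE)

#' @rdname shifting
#' @export
shift_upstream <- function(x, amount) shift_impl(x, amount, TRUE, TRUE)

#' @rdname shifting
#' @export
shift_downstream <- function(x, amount) shift_impl(x, amount, FALSE, TRUE)

#' Flank: new ranges adjacent to existing ones
#'
#' Generates, for every range, a new range of exactly `width` bases lying
#' immediately next to it on the chosen side (gap 0, no overlap with the
#' source): `flank_left()` gives `[start - width, start - 1]`,
#' `flank_right()` gives `[end + 1, end + width]`; `upstream`/`downstream`
#' resolve by strand as in shifting, which is the usual way to build promoter
#' regions upstream of genes. Metadata and strand are copied. Flanks falling
#' below coordinate 1 or past the sequence end raise an integrity error.
#'
#' @param x A `RangeTable`.
#' @param width Positive integer width of the flanking range.
#' @examples
#' flank_left(range_table("chr1", 10, 20), 3)                    # [7, 9]
#' flank_upstream(range_table("chr1", 100, 200, strand = "-"), 50) # [201, 250]
#' @name flanking
NULL

flank_impl <- function(x, width, left_on_plus, strand_aware) {
  stopifnot(inherits(x, "RangeTable"))
  if (!is_count(width, min = 1L)) {
    rt_stop("flank width must be a single positive integer", "rt_contract_error")
  }
  width <- as.integer(width)
  on_left <- rep(left_on_plus, nrow(x))
  if (strand_aware) on_left <- xor(on_left, x$strand == "-")
  df <- as.data.frame(x)
  s <- ifelse(on_left, df$start - width, df$end + 1L)
  df$end <- as.integer(ifelse(on_left, df$start - 1L, df$end + width))
  df$start <- as.integer(s)
  restore_groups(new_range_table(df, genome_info = get_genome_info(x)), x)
}

#' @rdname flanking
#' @export
flank_left <- function(x, width) flank_impl(x, width, TRUE, FALSE)

#' @rdname flanking
#' @export
flank_right <- function(x, width) flank_impl(x, width, FALSE, FALSE)

#' @rdname flanking
#' @export
flank_upstream <- function(x, width) flank_impl(x, width, TRUE, TRUE)

#' @rdname flanking
#' @export
flank_downstream <- function(x, width) flank_impl(x, width, FALSE, TRUE)
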