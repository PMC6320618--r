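# Shared fixtures and comparison helpers. Everything is generated in code;
# no files ship with the tests.

toy_gi <- function() genome_info(c(chrA = 10000L, chrB = 8000L), build = "toy1")

# Coordinate-and-metadata equality, ignoring attributes and row names.
strip_attrs <- function(df) {
  keep <- intersect(names(attributes(df)), c("names", "row.names", "class"))
  attributes(df) <- attributes(df)[keep]
  df
}

expect_ranges_equal <- function(a, b, ignore_meta = FALSE) {
  da <- strip_attrs(as.data.frame(a))
  db <- strip_attrs(as.data.frame(b))
  if (ignore_meta) {
    da <- da[c("seqnames", "start", "end")]
    db <- db[c("seqnames", "start", "end")]
  }
  rownames(da) <- NULL
  rownames(db) <- NULL
  expect_equal(da, db)
}

hits_df <- function(h) data.frame(query = h$query, subject = h$subject)

expect_hits_equal <- function(a, b) expect_equal(hits_df(a), hits_df(b))

# The classic join illustration: one subject range spanning three queries.
fig_queries <- function() {
  range_table("chr1", start = c(10, 30, 50, 200), end = c(20, 40, 60, 210),
              qid = paste0("x", 1:4))
}
fig_subject <- function() range_table("chr1", 15, 55, sid = "y1")

# Six hand-classified variants: 4 transitions, 2 transversions on chr1.
titv_fixture <- function() {
  range_table("chr1", start = 1:6, end = 1:6,
              REF = c("A", "G", "C", "T", "A", "G"),
              ALT = c("G", "A", "T", "C", "C", "T"))
}

# Convert per-base membership lists into a comparable canonical form.
base_set_of <- function(x, gi = NULL) {
  if (!is.null(gi)) x <- set_genome_info(x, gi)
  oracle_base_set(x)
}

random_pair <- function(seed, n = NULL, m = NULL, gi = toy_gi()) {
  set.seed(seed)
  n <- n %||% sample(20:120, 1)
  m <- m %||% sample(20:120, 1)
  list(
    x = simulate_ranges(range_sim_spec(seed = seed * 2L + 1L, n = n, genome = gi,
                                       width_range = c(1L, 80L))),
    y = simulate_ranges(range_sim_spec(seed = seed * 2L + 2L, n = m, genome = gi,
                                       width_range = c(1L, 80L)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
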