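# Core data model and column verbs.

test_that("construction enforces the coordinate invariants", {
  expect_s3_class(range_table("chr1", 5, 4), "RangeTable")   # width-0 is legal
  expect_error(range_table("chr1", 5, 3), class = "rt_integrity_error")
  expect_error(range_table("chr1", 0, 4), class = "rt_integrity_error")
  expect_error(range_table("chr1", 1, 4, strand = "x"), class = "rt_integrity_error")
  gi <- genome_info(c(chr1 = 100))
  expect_error(range_table("chr1", 90, 101, genome_info = gi),
               class = "rt_integrity_error")
  expect_error(range_table("chr2", 1, 10, genome_info = gi),
               class = "rt_integrity_error")
  expect_error(genome_info(c(chr1 = 0)), class = "rt_parse_error")
  expect_error(genome_info(c(chr1 = 5, chr1 = 6)), class = "rt_parse_error")
})

test_that("width is derived and cannot be stored", {
  x <- range_table("chr1", c(1, 5), c(10, 4))
  expect_identical(ranges_width(x), c(10L, 0L))
  expect_error(as_range_table(data.frame(seqnames = "c", start = 1, end = 3,
                                         strand = "+", width = 99)), NA)
  # as_range_table drops a redundant width column rather than storing it
  expect_false("width" %in% names(as_range_table(
    data.frame(seqnames = "c", start = 1, end = 3, width = 3))))
})

test_that("filter subsets rows, keeps order, metadata and genome", {
  gi <- toy_gi()
  x <- range_table("chrA", c(1, 11, 21), c(5, 15, 25), score = c(7, 9, 12),
                   genome_info = gi)
  out <- filter(x, score > 8)
  expect_identical(out$score, c(9, 12))
  expect_identical(get_genome_info(out), gi)
  expect_ranges_equal(filter(x, TRUE), x)
  expect_error(filter(x, nope > 1), class = "rt_name_error")
})

test_that("filter agrees with a brute-force row scan", {
  x <- simulate_ranges(range_sim_spec(seed = 11, n = 50))
  k <- 25
  out <- filter(x, width >= k)
  keep <- vapply(seq_len(nrow(x)),
                 function(i) (x$end[i] - x$start[i] + 1L) >= k, logical(1))
  expect_ranges_equal(out, x[keep, ])
})

test_that("composing filters equals filtering on the conjunction", {
  x <- simulate_ranges(range_sim_spec(seed = 12, n = 80))
  expect_ranges_equal(filter(filter(x, score > 30), width < 40),
                      filter(x, score > 30 & width < 40))
})

test_that("mutate adds columns and guards coordinate integrity", {
  x <- range_table("chr1", c(10, 20), c(19, 24), score = c(10, 5))
  out <- mutate(x, gc = score / width)
  expect_identical(out$gc, c(1, 1))
  expect_identical(ncol(out), ncol(x) + 1L)
  # assigning start/end recomputes width implicitly
  out2 <- mutate(x, end = end + 5L)
  expect_identical(ranges_width(out2), ranges_width(x) + 5L)
  expect_error(mutate(x, start = start - 100L), class = "rt_integrity_error")
  gi <- genome_info(c(chr1 = 30))
  expect_error(mutate(set_genome_info(x, gi), end = end + 20L),
               class = "rt_integrity_error")
})

test_that("transition classification matches hand enumeration of all 12 pairs", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(REF = bases, ALT = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$REF != pairs$ALT, ]
  # hand classification: purine<->purine or pyrimidine<->pyrimidine
  hand <- c("A>G" = TRUE, "G>A" = TRUE, "C>T" = TRUE, "T>C" = TRUE,
            "A>C" = FALSE, "A>T" = FALSE, "C>A" = FALSE, "C>G" = FALSE,
            "G>C" = FALSE, "G>T" = FALSE, "T>A" = FALSE, "T>G" = FALSE)
  x <- range_table("chr1", seq_len(12), seq_len(12),
                   REF = pairs$REF, ALT = pairs$ALT)
  out <- mutate(x, transition = (REF %in% c("A", "G") & ALT %in% c("A", "G")) |
                                (REF %in% c("C", "T") & ALT %in% c("C", "T")))
  expect_identical(out$transition,
                   unname(hand[paste0(pairs$REF, ">", pairs$ALT)]))
})

test_that("select restricts metadata but never the coordinates", {
  x <- range_table("chr1", 1, 10, a = 1, score = 2, b = 3)
  out <- select(x, score)
  expect_identical(names(out), c("seqnames", "start", "end", "strand", "score"))
  expect_ranges_equal(select(x, a, score, b), x)   # full selection is identity
  expect_ranges_equal(select(x), x)
  expect_error(select(x, -start), class = "rt_contract_error")
  expect_error(select(x, missing_col), class = "rt_name_error")
  expect_identical(names(select(x, -a)), c("seqnames", "start", "end", "strand",
                                           "score", "b"))
})

test_that("arrange sorts stably and agrees with an independent sort", {
  x <- range_table("chr1", c(30, 10, 20), c(39, 19, 29))
  expect_identical(arrange(x, start)$start, c(10L, 20L, 30L))
  x2 <- range_table("chr1", c(5, 3, 9), c(6, 4, 10), tag = c("a", "b", "c"))
  expect_identical(arrange(x2, seqnames)$tag, c("a", "b", "c"))  # stability
  r <- simulate_ranges(range_sim_spec(seed = 21, n = 100))
  out <- arrange(r, seqnames, start)
  o <- order(r$seqnames, r$start)   # independent lexicographic oracle
  expect_identical(out$start, r$start[o])
  expect_identical(out$seqnames, r$seqnames[o])
  expect_identical(arrange(x2, desc(start))$start, c(9L, 5L, 3L))
})

test_that("group_by partitions and summarise aggregates per group", {
  x <- range_table(c("chr1", "chr2", "chr1"), c(1, 2, 3), c(5, 6, 7),
                   score = c(2, 4, 6))
  g <- group_by(x, seqnames)
  out <- summarise(g, m = mean(score), k = n())
  expect_identical(out$seqnames, c("chr1", "chr2"))   # first-appearance order
  expect_identical(out$m, c(4, 4))
  expect_identical(out$k, c(2L, 1L))
  expect_ranges_equal(ungroup(g), x)
  expect_error(group_by(x, nothere), class = "rt_name_error")
  # constant key equals ungrouped summarise
  cx <- mutate(x, const = 1)
  expect_identical(summarise(group_by(cx, const), m = mean(score))$m,
                   summarise(cx, m = mean(score))$m)
})

test_that("group sizes and group means match hash-count and loop oracles", {
  r <- simulate_ranges(range_sim_spec(seed = 31, n = 150, metadata = c("score", "id")))
  out <- summarise(group_by(r, id), n = n(), m = mean(score))
  tally <- table(r$id)
  for (k in seq_len(nrow(out))) {
    expect_identical(out$n[k], as.integer(tally[[out$id[k]]]))
    expect_equal(out$m[k], mean(r$score[r$id == out$id[k]]))
  }
})

test_that("summarise returns a plain table and checks scalarity", {
  x <- titv_fixture()
  x <- mutate(x, transition = (REF %in% c("A", "G") & ALT %in% c("A", "G")) |
                              (REF %in% c("C", "T") & ALT %in% c("C", "T")))
  out <- summarise(group_by(x, seqnames),
                   titv = sum(transition) / sum(!transition))
  expect_false(inherits(out, "RangeTable"))
  expect_identical(out$titv, 2)
  expect_identical(summarise(x, total = n())$total, 6L)
  expect_error(summarise(x, bad = REF), class = "rt_shape_error")
})

test_that("verbs are endomorphic and never drop the genome", {
  gi <- toy_gi()
  x <- simulate_ranges(range_sim_spec(seed = 41, n = 40, genome = gi))
  pipelines <- list(
    function(z) filter(z, score > 10),
    function(z) mutate(z, s2 = score * 2),
    function(z) select(z, score),
    function(z) arrange(z, desc(score)),
    function(z) shift_right(z, 5),
    function(z) stretch(anchor_start(z), 3),
    function(z) reduce_ranges(z),
    function(z) flank_left(filter(z, start > 200), 10)
  )
  for (p in pipelines) {
    out <- p(x)
    expect_s3_class(out, "RangeTable")
    expect_silent(validate_range_table(out))
    expect_identical(seq_lengths(out), gi$seqlengths)
  }
})

test_that("grouped filter and mutate evaluate per group", {
  x <- range_table(c("chr1", "chr1", "chr2"), c(1, 10, 1), c(5, 14, 5),
                   score = c(1, 5, 10))
  g <- group_by(x, seqnames)
  top <- filter(g, score == max(score))
  expect_identical(top$score, c(5, 10))
  centered <- mutate(g, d = score - mean(score))
  expect_identical(centered$d, c(-2, 2, 0))
})
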