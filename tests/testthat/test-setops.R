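# Parallel and merging interval set operations.

test_that("parallel intersect/union/span/between follow the pairwise formulas", {
  a <- range_table("chr1", 1, 10)
  b <- range_table("chr1", 5, 20)
  expect_ranges_equal(a %intersect% b, range_table("chr1", 5, 10))
  expect_ranges_equal(a %intersect% a, a)
  expect_error(range_table("chr1", 1, 5) %intersect% range_table("chr1", 10, 12),
               class = "rt_pairing_error")
  # abutting pairs intersect in a width-0 range, not an error
  ab <- range_table("chr1", 1, 5) %intersect% range_table("chr1", 6, 9)
  expect_identical(ranges_width(ab), 0L)
  expect_error(range_table("chr1", 1, 5) %union% range_table("chr1", 10, 12),
               class = "rt_pairing_error")
  expect_ranges_equal(span(range_table("chr1", 1, 5), range_table("chr1", 10, 12)),
                      range_table("chr1", 1, 12))
  expect_ranges_equal(between(range_table("chr1", 1, 5), range_table("chr1", 10, 12)),
                      range_table("chr1", 6, 9))
  # adjacent pair: the gap is width-0
  expect_identical(ranges_width(between(range_table("chr1", 1, 5),
                                        range_table("chr1", 6, 9))), 0L)
  expect_error(range_table("chr1", 1, 5) %union% range_table("chr2", 1, 5),
               class = "rt_pairing_error")
  expect_error(a %union% range_table("chr1", c(1, 2), c(3, 4)),
               class = "rt_pairing_error")
})

test_that("parallel setdiff trims one side and rejects two-piece results", {
  expect_ranges_equal(range_table("chr1", 1, 10) %setdiff% range_table("chr1", 6, 20),
                      range_table("chr1", 1, 5))
  expect_ranges_equal(range_table("chr1", 1, 10) %setdiff% range_table("chr1", 11, 20),
                      range_table("chr1", 1, 10))
  expect_error(range_table("chr1", 1, 10) %setdiff% range_table("chr1", 3, 6),
               class = "rt_pairing_error")
  # full coverage leaves a width-0 remnant
  out <- range_table("chr1", 4, 6) %setdiff% range_table("chr1", 1, 10)
  expect_identical(ranges_width(out), 0L)
})

test_that("merging intersect/union/complement match the forced examples", {
  x <- range_table("chr1", c(1, 20), c(10, 30))
  y <- range_table("chr1", 5, 25)
  expect_ranges_equal(intersect_ranges(x, y),
                      range_table("chr1", c(5, 20), c(10, 25)), ignore_meta = TRUE)
  empty <- range_table(character(), integer(), integer())
  expect_ranges_equal(union_ranges(x, empty), reduce_ranges(x), ignore_meta = TRUE)
  gi <- genome_info(c(chr1 = 20))
  comp <- complement_ranges(range_table("chr1", 5, 10, genome_info = gi))
  expect_ranges_equal(comp, range_table("chr1", c(1, 11), c(4, 20)),
                      ignore_meta = TRUE)
  expect_error(complement_ranges(x), class = "rt_contract_error")
})

test_that("merging ops drop metadata, unstrand, and sort deterministically", {
  gi <- toy_gi()
  x <- simulate_ranges(range_sim_spec(seed = 61, n = 50, genome = gi))
  out <- union_ranges(x, x)
  expect_identical(names(out), c("seqnames", "start", "end", "strand"))
  expect_true(all(out$strand == "*"))
  o <- order(match(out$seqnames, names(seq_lengths(gi))), out$start)
  expect_identical(o, seq_len(nrow(out)))
})

test_that("merging ops agree with the per-base bitset oracle on random inputs", {
  gi <- genome_info(c(chrA = 5000L, chrB = 4000L))
  for (seed in 1:12) {
    p <- random_pair(seed, gi = gi)
    x <- p$x; y <- p$y
    bx <- oracle_base_set(x); by <- oracle_base_set(y)
    expect_identical(oracle_base_set(intersect_ranges(x, y)),
                     Map(`&`, bx, by))
    expect_identical(oracle_base_set(union_ranges(x, y)),
                     Map(`|`, bx, by))
    expect_identical(oracle_base_set(setdiff_ranges(x, y)),
                     Map(function(a, b) a & !b, bx, by))
    expect_identical(oracle_base_set(complement_ranges(x)),
                     lapply(bx, `!`))
  }
})

test_that("reduce merges overlapping and neighboring runs and aggregates", {
  x <- range_table("chr1", c(1, 4, 10), c(5, 8, 12))
  expect_ranges_equal(reduce_ranges(x),
                      range_table("chr1", c(1, 10), c(8, 12)), ignore_meta = TRUE)
  nb <- range_table("chr1", c(1, 6), c(5, 9))
  expect_ranges_equal(reduce_ranges(nb), range_table("chr1", 1, 9),
                      ignore_meta = TRUE)
  sc <- range_table("chr1", c(1, 4, 10), c(5, 8, 12), score = c(3, 8, 5))
  out <- reduce_ranges(sc, peak = max(score))
  expect_identical(out$peak, c(8, 5))
  # idempotence; sorted, disjoint, non-adjacent output
  x2 <- simulate_ranges(range_sim_spec(seed = 62, n = 120))
  r <- reduce_ranges(x2)
  expect_ranges_equal(reduce_ranges(r), r)
  by_seq <- split(seq_len(nrow(r)), r$seqnames)
  for (idx in by_seq) {
    if (length(idx) > 1L) {
      expect_true(all(r$start[idx][-1L] > r$end[idx][-length(idx)] + 1L))
    }
  }
  expect_error(reduce_ranges(sc, bad = score), class = "rt_shape_error")
})

test_that("grouped and directed reduce merge within their partitions", {
  x <- range_table("chr1", c(1, 4, 1, 4), c(6, 9, 6, 9),
                   strand = c("+", "-", "+", "-"), grp = c("a", "a", "b", "b"))
  out <- reduce_ranges(group_by(x, grp))
  expect_identical(out$grp, c("a", "b"))
  expect_identical(out$start, c(1L, 1L))
  dir <- reduce_ranges_directed(x)
  expect_identical(nrow(dir), 2L)
  expect_setequal(dir$strand, c("+", "-"))
  # undirected reduce ignores strand entirely
  expect_identical(nrow(reduce_ranges(x)), 1L)
})

test_that("disjoin partitions covered bases at every boundary", {
  x <- range_table("chr1", c(1, 5), c(10, 15))
  expect_ranges_equal(disjoin_ranges(x),
                      range_table("chr1", c(1, 5, 11), c(4, 10, 15)),
                      ignore_meta = TRUE)
  dj <- simulate_ranges(range_sim_spec(seed = 63, n = 30))
  sorted <- arrange(reduce_ranges(dj), seqnames, start)   # disjoint input
  expect_ranges_equal(disjoin_ranges(sorted),
                      arrange(sorted, seqnames, start), ignore_meta = TRUE)
  # piece-wise counts equal the per-base cover-count oracle at each piece
  x3 <- simulate_ranges(range_sim_spec(seed = 64, n = 100))
  out <- disjoin_ranges(x3, cov = n())
  oc <- oracle_coverage(x3)
  for (k in seq_len(nrow(out))) {
    seg <- oc[[out$seqnames[k]]][out$start[k]:out$end[k]]
    expect_true(all(seg == out$cov[k]))
  }
  # pieces disjoint; union equals reduce
  expect_ranges_equal(reduce_ranges(out), reduce_ranges(x3), ignore_meta = TRUE)
})

test_that("coverage tiles the genome with maximal constant-depth runs", {
  gi <- genome_info(c(chr1 = 10))
  cov <- compute_coverage(range_table("chr1", c(1, 3), c(5, 8), genome_info = gi))
  expect_identical(cov$start, c(1L, 3L, 6L, 9L))
  expect_identical(cov$end, c(2L, 5L, 8L, 10L))
  expect_identical(cov$score, c(1, 2, 1, 0))
  # empty input: one zero run per sequence
  e <- compute_coverage(range_table(character(), integer(), integer(),
                                    genome_info = gi))
  expect_identical(nrow(e), 1L)
  expect_identical(e$score, 0)
  expect_identical(ranges_width(e), 10L)
  # abutting equal-depth ranges collapse into one run
  cov2 <- compute_coverage(range_table("chr1", c(1, 6), c(5, 9), genome_info = gi))
  expect_identical(cov2$start, c(1L, 10L))
  # conservation + per-base oracle on random input
  x <- simulate_ranges(range_sim_spec(seed = 65, n = 80))
  cv <- compute_coverage(x)
  expect_equal(sum(cv$score * ranges_width(cv)), sum(ranges_width(x)))
  oc <- oracle_coverage(x)
  for (k in seq_len(nrow(cv))) {
    seg <- oc[[cv$seqnames[k]]][cv$start[k]:cv$end[k]]
    expect_true(all(seg == cv$score[k]))
  }
  # adjacent runs always change depth
  for (idx in split(seq_len(nrow(cv)), cv$seqnames)) {
    if (length(idx) > 1L) expect_true(all(diff(cv$score[idx]) != 0))
  }
})

test_that("union with the complement tiles each sequence exactly", {
  x <- simulate_ranges(range_sim_spec(seed = 66, n = 60))
  gi <- get_genome_info(x)
  tiled <- union_ranges(x, complement_ranges(x))
  expect_identical(tiled$seqnames, names(seq_lengths(gi)))
  expect_identical(tiled$start, rep(1L, 2))
  expect_identical(tiled$end, unname(seq_lengths(gi)))
})

test_that("coverage islands recover reduce: the peak-finding backbone", {
  x <- simulate_ranges(range_sim_spec(seed = 67, n = 70))
  cov <- compute_coverage(x)
  islands <- reduce_ranges(filter(cov, score > 0))
  expect_ranges_equal(islands, reduce_ranges(x), ignore_meta = TRUE)
})
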