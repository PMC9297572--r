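test_that("window tiling follows the fixed-width-with-partial-tail rule", {
  idx <- genome_index("c1", 2500)
  w <- make_windows(idx, 1000)
  expect_equal(w$start, c(0, 1000, 2000))
  expect_equal(w$end, c(1000, 2000, 2500))

  w1 <- make_windows(genome_index("c1", 1000), 1000)
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start, w1$end), c(0, 1000))

  idx2 <- genome_index(c("c1", "c2"), c(1500, 500))
  w2 <- make_windows(idx2, 1000)
  expect_equal(nrow(w2), 3)
  # conservation: window lengths partition the genome
  expect_equal(sum(w2$end - w2$start), sum(idx2$length))

  expect_error(make_windows(idx, 0), "window_size")
})

test_that("merge unions overlapping and touching intervals, per chromosome", {
  expect_equal(merge_intervals(intervals(c("c1", "c1"), c(0, 5), c(10, 15))),
               intervals("c1", 0, 15))
  expect_equal(merge_intervals(intervals(c("c1", "c1"), c(0, 10), c(10, 20))),
               intervals("c1", 0, 20))
  x <- intervals(c("c1", "c2"), c(0, 0), c(10, 10))
  expect_equal(merge_intervals(x), x)
  # idempotence
  y <- intervals(rep("c1", 4), c(0, 5, 30, 40), c(12, 20, 42, 50))
  expect_identical(merge_intervals(merge_intervals(y)), merge_intervals(y))
})

test_that("intersect_length and coverage_fraction follow base arithmetic", {
  expect_equal(intersect_length(intervals("c1", 0, 100),
                                intervals("c1", 50, 150)), 50)
  expect_equal(intersect_length(intervals("c1", 0, 10),
                                intervals("c2", 0, 10)), 0)
  a <- intervals(c("c1", "c1"), c(0, 200), c(100, 300))
  expect_equal(intersect_length(a, a), 200)
  expect_equal(intersect_length(a, intervals("c1", 50, 250)),
               intersect_length(intervals("c1", 50, 250), a))

  expect_equal(coverage_fraction(intervals("c1", 100, 200),
                                 intervals("c1", 100, 150)), 0.5)
  expect_equal(coverage_fraction(intervals("c1", 100, 200),
                                 intervals("c1", 0, 500)), 1.0)
  # overlapping mask pieces are merged before counting
  expect_equal(coverage_fraction(intervals("c1", 100, 200),
                                 intervals(c("c1", "c1"), c(90, 110), c(120, 160))),
               0.6)
})

test_that("total_masked_bases counts nested and duplicated elements once", {
  expect_equal(total_masked_bases(ra("c1", c(0, 500), c(100, 600))), 200)
  expect_equal(total_masked_bases(ra("c1", c(0, 0), c(100, 100))), 100)
  # invariance under splitting an element at interior points
  whole <- ra("c1", 100, 400)
  split3 <- ra("c1", c(100, 200, 300), c(200, 300, 400))
  expect_equal(total_masked_bases(whole), total_masked_bases(split3))
})

test_that("interval algebra agrees exactly with the per-base oracle", {
  idx <- genome_index(c("c1", "c2"), c(8000, 5000))
  set.seed(42)
  for (rep in 1:200) {
    a <- rand_intervals(idx)
    b <- rand_intervals(idx)
    expect_identical(merge_intervals(a),
                     {
                       m <- oracle_merge(a, idx)
                       rownames(m) <- NULL
                       m[order(m$chrom, m$start, method = "radix"), ]
                     })
    expect_equal(intersect_length(a, b), oracle_intersect_bases(a, b, idx))
    expect_equal(total_masked_bases(cbind(a, te_class = "Unknown",
                                          superfamily = "", source = "t")),
                 oracle_total_bases(a, idx))
    t1 <- a[1, , drop = FALSE]
    expect_equal(coverage_fraction(t1, b), oracle_coverage_fraction(t1, b, idx))
  }
})

test_that("coverage_fraction is monotone as mask intervals accumulate", {
  set.seed(7)
  idx <- genome_index("c1", 5000)
  target <- intervals("c1", 1000, 2000)
  mask <- rand_intervals(idx, n_max = 30)
  fr <- vapply(seq_len(nrow(mask)), function(k)
    coverage_fraction(target, mask[seq_len(k), , drop = FALSE]), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("interval validation rejects malformed and out-of-range records", {
  expect_error(intervals("c1", 10, 10), "start < end")
  expect_error(intervals("c1", -1, 5), "start < end")
  idx <- genome_index("c1", 100)
  expect_error(intervals("c1", 50, 150, index = idx), "beyond chromosome length")
  expect_error(intervals("c9", 0, 10, index = idx), "not in genome index")
  expect_error(repeat_annotation("c1", 0, 10, "NotAClass"), "unknown TE class")
  expect_error(repeat_annotation("c1", 0, 10, "Simple_repeat", "CR1"),
               "without superfamilies")
})
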