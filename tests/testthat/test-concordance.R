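test_that("window binarization uses the any-overlap rule", {
  idx <- genome_index("c1", 3000)
  grid <- make_windows(idx, 1000)
  pm <- binarize_windows(list(toolA = ra("c1", 1500, 1600)), grid, idx)
  expect_equal(unname(pm$values[, "toolA"]), c(0L, 1L, 0L))

  # boundary-spanning element sets both windows
  pm2 <- binarize_windows(list(toolA = ra("c1", 999, 1001)), grid, idx)
  expect_equal(unname(pm2$values[, "toolA"]), c(1L, 1L, 0L))

  # empty set gives an all-zero column
  empty <- repeat_annotation(character(), numeric(), numeric(), source = "e")
  pm3 <- binarize_windows(list(toolA = ra("c1", 0, 10), e = empty), grid, idx)
  expect_equal(unname(pm3$values[, "e"]), c(0L, 0L, 0L))

  # configurable minimum masked bases
  pm4 <- binarize_windows(list(toolA = ra("c1", 999, 1001)), grid, idx,
                          min_bases = 2)
  expect_equal(unname(pm4$values[, "toolA"]), c(0L, 0L, 0L))
})

test_that("per-method 1-counts equal per-base oracle window counts", {
  idx <- genome_index(c("c1", "c2"), c(7000, 4000))
  grid <- make_windows(idx, 1000)
  set.seed(11)
  for (rep in 1:20) {
    x <- rand_intervals(idx, n_max = 25)
    aset <- cbind(x, te_class = "Unknown", superfamily = "", source = "t")
    pm <- binarize_windows(list(t = aset), grid, idx)
    oracle <- vapply(seq_len(nrow(grid)), function(i) {
      v <- oracle_vec(x, grid$chrom[i], idx$length[idx$chrom == grid$chrom[i]])
      any(v[(grid$start[i] + 1):grid$end[i]])
    }, logical(1))
    expect_equal(unname(pm$values[, "t"]), as.integer(oracle))
  }
})

test_that("complete-linkage clustering of methods is exact and deterministic", {
  idx <- genome_index("c1", 3000)
  grid <- make_windows(idx, 1000)
  a <- ra("c1", c(0, 1100), c(50, 1200))
  sets <- list(m1 = a, m2 = a, m3 = ra("c1", 2100, 2200))
  pm <- binarize_windows(sets, grid, idx)
  hc <- cluster_methods(pm)
  expect_equal(hc$height[1], 0)  # identical columns merge first, at height 0

  # closed-form Euclidean distance between all-zero and all-one columns
  empty <- repeat_annotation(character(), numeric(), numeric(), source = "z")
  full <- ra("c1", c(0, 1000, 2000), c(500, 1500, 2500))
  pm2 <- binarize_windows(list(zero = empty, one = full), grid, idx)
  hc2 <- cluster_methods(pm2)
  expect_equal(hc2$height, sqrt(3))

  expect_error(cluster_methods(binarize_windows(list(only = a), grid, idx)),
               "at least 2")
})

test_that("dendrogram is invariant under permutation of method input order", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(c1 = 2e5))
  suite <- simulate_annotation_suite(cfg)
  grid <- make_windows(suite$index, 1000)
  pm1 <- binarize_windows(suite$tools, grid, suite$index)
  perm <- rev(names(suite$tools))
  pm2 <- binarize_windows(suite$tools[perm], grid, suite$index)
  h1 <- cluster_methods(pm1); h2 <- cluster_methods(pm2)
  expect_identical(h1$merge, h2$merge)
  expect_identical(h1$height, h2$height)
  expect_identical(h1$labels, h2$labels)
})

test_that("pattern ranking excludes the all-zero pattern and counts exactly", {
  pm <- list(methods = c("a", "b", "c"),
             values = rbind(matrix(rep(c(1L, 1L, 0L), 2), 2, byrow = TRUE),
                            c(0L, 0L, 1L),
                            matrix(0L, 5, 3)))
  colnames(pm$values) <- pm$methods
  top <- pattern_abundance(pm, 2)
  expect_equal(top$pattern, c("110", "001"))
  expect_equal(top$count, c(2L, 1L))

  pm1 <- list(methods = "a", values = matrix(1L, 4, 1, dimnames = list(NULL, "a")))
  expect_equal(pattern_abundance(pm1, 5),
               data.frame(pattern = "1", a = 1L, count = 4L))

  # random fixture against a dictionary-count oracle
  set.seed(3)
  v <- matrix(rbinom(1000 * 4, 1, 0.3), 1000, 4,
              dimnames = list(NULL, letters[1:4]))
  pm2 <- list(methods = letters[1:4], values = v)
  top2 <- pattern_abundance(pm2, 1000)
  key <- apply(v, 1, paste0, collapse = "")
  dict <- sort(table(key[key != "0000"]), decreasing = TRUE)
  expect_equal(sum(top2$count), sum(dict))
  expect_equal(stats::setNames(top2$count, top2$pattern)[names(dict)],
               stats::setNames(as.integer(dict), names(dict)))
})

test_that("pairwise agreement is normalized by the compared method", {
  a <- ra("c1", 10, 60)
  refbig <- ra("c1", 0, 100)
  expect_equal(pairwise_agreement(a, refbig), 1.0)     # subset
  expect_equal(pairwise_agreement(a, a), 1.0)          # identity
  expect_equal(pairwise_agreement(a, ra("c1", 500, 600)), 0.0)  # disjoint
  expect_equal(pairwise_agreement(ra("c1", 0, 100), ra("c1", 50, 150)), 0.5)
  # asymmetry: the denominator is the compared method's mask
  expect_equal(pairwise_agreement(refbig, a), 0.5)
  empty <- repeat_annotation(character(), numeric(), numeric(), source = "e")
  expect_error(pairwise_agreement(empty, a), "empty")

  idx <- genome_index("c1", 3000)
  grid <- make_windows(idx, 1000)
  wa <- pairwise_agreement(ra("c1", c(100, 1100), c(200, 1200)),
                           ra("c1", 150, 180), mode = "window",
                           grid = grid, index = idx)
  expect_equal(wa, 0.5)
})

test_that("coverage summary merges before summing", {
  idx <- genome_index("c1", 100000)
  one <- ra("c1", c(0, 50000), c(6000, 56000))
  cs <- coverage_summary(list(m = one), idx)
  expect_equal(cs$masked_bp, 12000)
  expect_equal(cs$genome_fraction, 0.12)
  dup <- rbind(one, one)
  expect_equal(coverage_summary(list(m = dup), idx)$masked_bp, 12000)
})
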