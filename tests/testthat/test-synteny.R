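ord <- function(species, fams) {
  gene_order(species, "S1", seq_along(fams),
             paste0(species, "_", seq_along(fams)), fams)
}

test_that("gene-order alignment chains single-copy families", {
  a <- ord("A", c("x", "y", "z"))
  b <- ord("B", c("x", "y", "z"))
  al <- align_gene_orders(a, b)
  expect_equal(al$family, c("x", "y", "z"))
  expect_equal(attr(al, "orientation"), "forward")

  # inverted scaffold recovered through the reverse orientation
  br <- ord("B", c("z", "y", "x"))
  alr <- align_gene_orders(a, br)
  expect_equal(alr$family, c("x", "y", "z"))
  expect_equal(attr(alr, "orientation"), "reverse")

  # multi-copy families never anchor
  am <- ord("A", c("x", "M", "y", "M", "z"))
  bm <- ord("B", c("x", "y", "z"))
  expect_equal(align_gene_orders(am, bm)$family, c("x", "y", "z"))
})

test_that("alignment length equals the quadratic LCS dynamic program", {
  set.seed(53)
  for (rep in 1:25) {
    fa <- sample(sprintf("F%02d", 1:50))
    fb <- sample(sprintf("F%02d", 1:50))
    al <- align_gene_orders(ord("A", fa), ord("B", fb))
    expect_equal(nrow(al),
                 max(oracle_lcs_length(fa, fb), oracle_lcs_length(fa, rev(fb))))
    # the chain is a genuine common subsequence in the kept orientation
    pb <- if (attr(al, "orientation") == "reverse") -al$pos_b else al$pos_b
    expect_true(all(diff(al$pos_a) > 0) && all(diff(pb) > 0))
  }
  # a planted 30-token common subsequence is always found
  set.seed(59)
  core <- sprintf("C%02d", 1:30)
  fa <- character(0); fb <- character(0)
  extra_a <- sprintf("A%02d", 1:20); extra_b <- sprintf("B%02d", 1:20)
  sa <- sort(sample(50, 30)); sb <- sort(sample(50, 30))
  fa <- character(50); fa[sa] <- core; fa[-sa] <- extra_a
  fb <- character(50); fb[sb] <- core; fb[-sb] <- extra_b
  expect_gte(nrow(align_gene_orders(ord("A", fa), ord("B", fb))), 30)
})

test_that("lineage-specific insertions require absence from both outgroups", {
  focal <- ord("P", c("a", "b", "Z", "c"))
  o1 <- ord("Q", c("a", "b", "c"))
  o2 <- ord("R", c("a", "b", "c"))
  calls <- detect_lineage_specific_insertions(focal, o1, o2, "Z")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$left_anchor, "b")
  expect_equal(calls$right_anchor, "c")
  expect_equal(calls$supported_by, "Q,R")

  # present in one outgroup: no call
  o1z <- ord("Q", c("a", "b", "Z", "c"))
  expect_equal(nrow(detect_lineage_specific_insertions(focal, o1z, o2, "Z")), 0)
})

test_that("calls depend only on family tokens, not gene ids", {
  fix <- simulate_gene_orders(sim_config(seed = 61, shuffle_rate = 0))
  c1 <- detect_lineage_specific_insertions(fix$focal, fix$out1, fix$out2,
                                           "ZISUPTON")
  relab <- fix$focal
  relab$gene_id <- paste0("renamed_", seq_len(nrow(relab)))
  c2 <- detect_lineage_specific_insertions(relab, fix$out1, fix$out2,
                                           "ZISUPTON")
  expect_equal(c1[, c("scaffold", "family", "left_anchor", "right_anchor")],
               c2[, c("scaffold", "family", "left_anchor", "right_anchor")])
})

test_that("noise-free fixtures are recovered with perfect precision and recall", {
  fix <- simulate_gene_orders(sim_config(seed = 67, shuffle_rate = 0))
  calls <- detect_lineage_specific_insertions(fix$focal, fix$out1, fix$out2,
                                              "ZISUPTON")
  called <- unlist(strsplit(calls$gene_ids, ","))
  expect_setequal(called, fix$registry$gene_id)       # recall 1, precision 1
  # soundness: no called gene's family occurs between the anchors in outgroups
  for (k in seq_len(nrow(calls))) {
    for (og in list(fix$out1, fix$out2)) {
      p <- sort(c(og$position[og$family == calls$left_anchor[k]],
                  og$position[og$family == calls$right_anchor[k]]))
      mid <- og$family[og$position > p[1] & og$position < p[2]]
      expect_false("ZISUPTON" %in% mid)
    }
  }
})

test_that("local shuffling degrades recall only mildly and never precision", {
  hits <- 0; total <- 0; false_calls <- 0
  for (s in 1:10) {
    fix <- simulate_gene_orders(sim_config(seed = 100 + s, shuffle_rate = 0.05))
    calls <- detect_lineage_specific_insertions(fix$focal, fix$out1, fix$out2,
                                                "ZISUPTON")
    called <- unlist(strsplit(calls$gene_ids, ","))
    hits <- hits + sum(fix$registry$gene_id %in% called)
    total <- total + nrow(fix$registry)
    false_calls <- false_calls + sum(!called %in% fix$registry$gene_id)
  }
  expect_equal(false_calls, 0)
  expect_gte(hits / total, 0.9)
})
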