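test_that("isoform merging unions exons per gene", {
  g <- gm("g1", c("t1", "t2"), "c1", c(0, 50), c(100, 150))
  m <- merge_isoforms(g)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 150))
  expect_equal(m$transcript_id, "g1.merged")

  single <- gm("g1", "t1", "c1", 0, 100)
  ms <- merge_isoforms(single)
  expect_equal(c(ms$start, ms$end), c(0, 100))

  dis <- gm("g1", c("t1", "t2"), "c1", c(0, 200), c(100, 300))
  expect_equal(nrow(merge_isoforms(dis)), 2)
})

test_that("full containment is exact at the base level", {
  aset <- ra("c1", 100, 200)
  hit <- function(genes) nrow(fully_contained_overlaps(genes, aset))
  expect_equal(hit(gm("g1", "t1", "c1", 100, 200)), 1)  # exact fit
  aset2 <- ra("c1", 90, 210)
  expect_equal(nrow(fully_contained_overlaps(gm("g1", "t1", "c1", 100, 200), aset2)), 1)
  aset3 <- ra("c1", 100, 199)
  expect_equal(nrow(fully_contained_overlaps(gm("g1", "t1", "c1", 100, 200), aset3)), 0)

  multi <- gm("g1", c("t1", "t1"), "c1", c(0, 300), c(100, 400))
  expect_error(fully_contained_overlaps(multi, aset), "multi-exon")
})

test_that("containment against merged masks tolerates fragmented elements", {
  frag <- repeat_annotation("c1", c(100, 150), c(150, 200), "LINE", "CR1", "t")
  exon <- gm("g1", "t1", "c1", 110, 190)
  expect_equal(nrow(fully_contained_overlaps(exon, frag)), 1)
  # the raw-element mode requires one element to span the exon
  expect_equal(nrow(fully_contained_overlaps(exon, frag, raw_elements = TRUE)), 0)
  # counts invariant under splitting an element into abutting fragments
  whole <- repeat_annotation("c1", 100, 200, "LINE", "CR1", "t")
  expect_equal(fully_contained_overlaps(exon, frag)$covered_fraction,
               fully_contained_overlaps(exon, whole)$covered_fraction)
})

test_that("coverage threshold is inclusive at the boundary", {
  aset <- ra("c1", 0, 50)
  qualifies <- exon_coverage_overlaps(gm("g1", "t1", "c1", 0, 100), aset, 0.5)
  expect_equal(nrow(qualifies), 1)
  expect_equal(qualifies$covered_fraction, 0.5)
  short <- ra("c1", 0, 49)
  expect_equal(nrow(exon_coverage_overlaps(gm("g1", "t1", "c1", 0, 100), short, 0.5)), 0)

  # gene qualifies through any one exon
  g <- gm("g1", c("t1", "t1"), "c1", c(0, 200), c(100, 300))
  aset2 <- ra("c1", c(0, 200), c(40, 260))  # fractions 0.4 and 0.6
  rec <- exon_coverage_overlaps(g, aset2, 0.5)
  expect_equal(nrow(rec), 1)
  expect_equal(overlapping_genes(rec), "g1")
  expect_error(exon_coverage_overlaps(g, aset2, 0), "min_frac")
})

test_that("containment and min_frac=1 coverage coincide on single-exon input", {
  cfg <- sim_config(seed = 2)
  gf <- simulate_gene_fixture(cfg)
  se <- gf$genes[gf$genes$gene_id %in%
    gf$registry$gene_id[gf$registry$kind != "multi"], ]
  a <- fully_contained_overlaps(se, gf$repeats)
  b <- exon_coverage_overlaps(se, gf$repeats, min_frac = 1)
  expect_equal(a[order(a$gene_id, a$te_class), ],
               b[order(b$gene_id, b$te_class), ], ignore_attr = TRUE)
})

test_that("superfamily tally deduplicates transcripts and applies the cutoff", {
  recs <- data.frame(
    gene_id = "g", transcript_id = c(paste0("t", 1:35), paste0("u", 1:25),
                                     paste0("v", 1:5), "t1"),
    te_class = c(rep("LINE", 35), rep("DNA", 25), rep("LINE", 5), "LINE"),
    superfamily = c(rep("CR1", 35), rep("Sola-3", 25), rep("Vingi", 5), "CR1"),
    stringsAsFactors = FALSE)
  tal <- superfamily_tally(recs, 20)
  expect_equal(tal$superfamily, c("CR1", "Sola-3"))
  expect_equal(tal$n_transcripts, c(35L, 25L))  # duplicate t1/CR1 counted once

  expect_equal(nrow(superfamily_tally(recs, 100)), 0)
})

test_that("overlap pipeline reproduces the fixture registry exactly", {
  cfg <- sim_config(seed = 31)
  gf <- simulate_gene_fixture(cfg)
  reg <- gf$registry
  se <- gf$genes[gf$genes$gene_id %in% reg$gene_id[reg$kind != "multi"], ]

  ct <- fully_contained_overlaps(se, gf$repeats)
  planted_ct <- reg[reg$kind == "contained", ]
  expect_equal(nrow(ct), nrow(planted_ct))
  expect_setequal(ct$transcript_id, planted_ct$transcript_id)
  expect_equal(
    stats::setNames(ct$superfamily, ct$transcript_id)[planted_ct$transcript_id],
    stats::setNames(planted_ct$superfamily, planted_ct$transcript_id))

  cov <- exon_coverage_overlaps(merge_isoforms(gf$genes), gf$repeats, 0.5)
  planted_cov <- reg[reg$kind %in% c("contained", "half"), ]
  expect_setequal(cov$gene_id, planted_cov$gene_id)
  half <- cov[cov$gene_id %in% reg$gene_id[reg$kind == "half"], ]
  expect_true(all(half$covered_fraction == 0.5))

  tal <- superfamily_tally(ct, 20)
  planted_counts <- cfg$n_contained_per_superfamily
  expect_setequal(tal$superfamily, names(planted_counts)[planted_counts >= 20])
  expect_equal(stats::setNames(tal$n_transcripts, tal$superfamily),
               planted_counts[planted_counts >= 20][tal$superfamily])
})
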