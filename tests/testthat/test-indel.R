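test_that("indel classification honors the window and strand conventions", {
  gp <- list(gene_id = "g1", chrom = "c1", start = 1001L, end = 2000L,
             strand = "+")
  up <- classify_indel(gp, list(chrom = "c1", start = 950L, end = 960L), 1000L)
  expect_equal(up$region, "upstream")
  expect_equal(up$distance, 41L)
  genic <- classify_indel(gp, list(chrom = "c1", start = 1500L, end = 1501L), 1000L)
  expect_equal(genic$region, "genic")
  expect_equal(genic$distance, 0L)
  gm <- list(gene_id = "g2", chrom = "c1", start = 1001L, end = 2000L,
             strand = "-")
  upm <- classify_indel(gm, list(chrom = "c1", start = 2050L, end = 2060L), 1000L)
  expect_equal(upm$region, "upstream")
  expect_equal(upm$distance, 50L)
  # boundary-overlapping indel is genic (genic precedence)
  edge <- classify_indel(gp, list(chrom = "c1", start = 995L, end = 1001L), 1000L)
  expect_equal(edge$region, "genic")
  # outside the window, or other chromosome: no classification
  expect_null(classify_indel(gp, list(chrom = "c1", start = 4000L, end = 4001L), 1000L))
  expect_null(classify_indel(gp, list(chrom = "c2", start = 1500L, end = 1501L), 1000L))
})

test_that("mirror reflection with strand flip preserves classifications", {
  set.seed(701)
  M <- 100000L
  for (i in 1:40) {
    gs <- sample(10000:50000, 1); ge <- gs + sample(500:3000, 1)
    strand <- sample(c("+", "-"), 1)
    is <- sample((gs - 2000):(ge + 2000), 1); ie <- is + sample(0:20, 1)
    g <- list(gene_id = "g", chrom = "c", start = gs, end = ge, strand = strand)
    ind <- list(chrom = "c", start = is, end = ie)
    gr <- list(gene_id = "g", chrom = "c", start = M - ge, end = M - gs,
               strand = if (strand == "+") "-" else "+")
    indr <- list(chrom = "c", start = M - ie, end = M - is)
    a <- classify_indel(g, ind, 1000L)
    b <- classify_indel(gr, indr, 1000L)
    if (is.null(a)) {
      expect_null(b)
    } else {
      expect_equal(a$region, b$region)
      expect_equal(a$distance, b$distance)
    }
  }
})

test_that("pair classification agrees with per-base brute force", {
  set.seed(702)
  genes <- generate_gene_models(sprintf("g%03d", 1:50), seed = 71)
  span <- max(genes$end) + 2000L
  indels <- data.frame(chrom = "chr1",
                       start = sample(span, 300, replace = TRUE),
                       kind = "deletion", stringsAsFactors = FALSE)
  indels$end <- indels$start + sample(0:15, 300, replace = TRUE)
  pairs <- gene_indel_pairs(genes, indels, 1000L)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    for (j in seq_len(nrow(indels))) {
      want <- brute_indel_region(g, indels[j, ], 1000L)
      got <- pairs$region[pairs$gene_id == g$gene_id & pairs$indel_index == j]
      if (is.null(want)) {
        expect_equal(length(got), 0L)
      } else {
        expect_equal(got, want, info = paste(i, j))
      }
    }
  }
})

test_that("the 18/9/3-of-28 fixture reproduces the expected percentages", {
  flags <- data.frame(gene_id = sprintf("gst%02d", 1:28),
                      has_upstream = rep(c(TRUE, FALSE), c(18, 10)),
                      has_genic = rep(c(FALSE, TRUE, FALSE), c(10, 9, 9)),
                      has_downstream = rep(c(FALSE, TRUE), c(25, 3)),
                      stringsAsFactors = FALSE)
  pct <- indel_region_summary(flags)
  expect_equal(unname(pct["upstream"]), 64.29)
  expect_equal(unname(pct["genic"]), 32.14)
  expect_equal(unname(pct["downstream"]), 10.71)
})

test_that("the CIP x InDel intersection is contained in both sets", {
  genes <- generate_gene_models(sprintf("g%03d", 1:40), seed = 73)
  ind <- generate_indels(genes, rep(c(TRUE, FALSE), 20), 1000L, seed = 74,
                         background_rate = 0.1)
  flags <- genes_with_indels(genes, ind$indels, 1000L)
  cip_genes <- genes$gene_id[seq(1, 40, by = 2)]
  both <- intersect_cip_indel(cip_genes, flags)
  expect_true(all(both$gene_id %in% cip_genes))
  flagged <- flags$gene_id[flags$has_upstream | flags$has_genic | flags$has_downstream]
  expect_true(all(both$gene_id %in% flagged))
  # no indels: empty intersection
  empty <- genes_with_indels(genes, ind$indels[0, ], 1000L)
  expect_equal(nrow(intersect_cip_indel(cip_genes, empty)), 0L)
})
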