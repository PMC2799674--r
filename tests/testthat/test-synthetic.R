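test_that("genome pair generation is seeded and honors zero rates", {
  gp0 <- generate_genome_pair(2000, 0, 0, seed = 11)
  expect_identical(gp0$seq_a, gp0$seq_b)
  expect_equal(nrow(gp0$variants), 0L)

  gp1 <- generate_genome_pair(5000, 0.01, 0.001, seed = 12)
  gp2 <- generate_genome_pair(5000, 0.01, 0.001, seed = 12)
  expect_identical(gp1, gp2)
  expect_error(generate_genome_pair(500, 0, 0, 1), ">= 1000")
  expect_error(generate_genome_pair(2000, 0.5, 0, 1), "rates")
})

test_that("variant counts follow the generator's binomial rule", {
  gp <- generate_genome_pair(10000, 0.005, 0, seed = 21)
  n <- nrow(gp$variants)
  expect_gte(n, 50 - 4 * sqrt(50))
  expect_lte(n, 50 + 4 * sqrt(50))
  expect_true(all(gp$variants$type == "snp"))
})

test_that("probes are genome substrings with footprint-derived polymorphism", {
  gp <- generate_genome_pair(5000, 0, 0, seed = 31)
  pr <- generate_probes(gp, 12L, 5L, 25L, seed = 32)
  expect_equal(length(pr$probes), 12L * 5L)
  expect_equal(nrow(pr$map), 12L * 5L)
  expect_false(any(pr$probe_truth$is_polymorphic))
  expect_true(all(vapply(seq_along(pr$probes), function(i) {
    substr(gp$seq_a, pr$probe_truth$start[i], pr$probe_truth$end[i]) ==
      pr$probes[[i]]
  }, logical(1))))
  expect_error(generate_probes(gp, 500L, 11L, 25L, seed = 1), "too short")
})

test_that("polymorphic probes really differ between the genomes", {
  gp <- generate_genome_pair(6000, 0.01, 0.001, seed = 41)
  pr <- generate_probes(gp, 15L, 5L, 25L, seed = 42)
  cls <- classify_probes(pr$probes, gp$seq_a, gp$seq_b)
  poly <- pr$probe_truth$is_polymorphic
  # non-polymorphic probes hit both genomes; polymorphic ones lose genome B
  expect_true(all(cls$status[!poly] == "both"))
  expect_true(mean(cls$status[poly] == "a_only") > 0.9)
})

test_that("intensity model reduces to its null and forced cases", {
  map <- data.frame(probe_id = sprintf("PS%d_p%d", rep(1:4, each = 3), 1:3),
                    probeset_id = sprintf("PS%d", rep(1:4, each = 3)),
                    probe_index = rep(1:3, 4), stringsAsFactors = FALSE)
  design <- make_design(3L)
  probes <- data.frame(probe_id = map$probe_id, is_polymorphic = FALSE,
                       stringsAsFactors = FALSE)
  # sigma -> 0, no effects: the four cell means agree per probe
  sc <- sim_scenario(noise_sd = 1e-9, cip_fraction = 0, rng_seed = 5)
  sets <- data.frame(probeset_id = unique(map$probeset_id), is_cip = FALSE,
                     quadrant = "none", stringsAsFactors = FALSE)
  m <- generate_intensities(sc, map, list(sets = sets, probes = probes), design)
  lg <- log2(m)
  for (cell in split(design$array_id, paste(design$genotype, design$treatment))) {
    expect_equal(rowMeans(lg[, cell]), rowMeans(lg[, design$array_id[1:3]]),
                 tolerance = 1e-6)
  }
  # planted cultivar-only effect of 1: exact log2 genotype difference
  sc2 <- sim_scenario(noise_sd = 1e-9, delta_cultivar = 1,
                      delta_treatment = 0, delta_interaction = 0, rng_seed = 5)
  sets2 <- sets; sets2$is_cip <- TRUE; sets2$quadrant <- "prefA_up"
  m2 <- generate_intensities(sc2, map, list(sets = sets2, probes = probes), design)
  lg2 <- log2(m2)
  gA <- design$array_id[design$genotype == design$genotype[1]]
  gB <- setdiff(design$array_id, gA)
  expect_equal(unname(rowMeans(lg2[, gA]) - rowMeans(lg2[, gB])),
               rep(1, nrow(lg2)), tolerance = 1e-6)
  # determinism
  m3 <- generate_intensities(sc2, map, list(sets = sets2, probes = probes), design)
  expect_identical(m2, m3)
  # unbalanced designs are rejected
  expect_error(generate_intensities(sc2, map,
                                    list(sets = sets2, probes = probes),
                                    design[-1, ]), "balanced")
})

test_that("whole datasets are reproducible from the seed", {
  d1 <- simulate_dataset(sim_scenario(n_probesets = 20L, rng_seed = 77))
  d2 <- simulate_dataset(sim_scenario(n_probesets = 20L, rng_seed = 77))
  expect_identical(d1$intensities, d2$intensities)
  expect_identical(d1$annotations, d2$annotations)
  expect_identical(d1$promoters, d2$promoters)
  expect_identical(d1$indels, d2$indels)
  expect_equal(mean(d1$truth$sets$is_cip), 0.1, tolerance = 0.051)
})

test_that("annotations plant one enriched category at the stated odds", {
  sets <- data.frame(probeset_id = sprintf("PS%04d", 1:1000),
                     is_cip = rep(c(TRUE, FALSE), c(500, 500)),
                     quadrant = "none", stringsAsFactors = FALSE)
  ann <- generate_annotations(sets, 10L, enriched_odds = 10, seed = 9,
                              base_rate = 0.05)
  enr <- ann$annotations[ann$annotations$category_id == ann$enriched_category, ]
  rate_cip <- mean(sets$probeset_id[sets$is_cip] %in% enr$item_id)
  rate_bg <- mean(sets$probeset_id[!sets$is_cip] %in% enr$item_id)
  expect_gt(rate_cip, 3 * rate_bg)
  # odds 1: enriched category indistinguishable from the base rate
  ann1 <- generate_annotations(sets, 10L, enriched_odds = 1, seed = 9,
                               base_rate = 0.05)
  enr1 <- ann1$annotations[ann1$annotations$category_id == ann1$enriched_category, ]
  rate1 <- mean(sets$probeset_id[sets$is_cip] %in% enr1$item_id)
  expect_lt(abs(rate1 - 0.05), 0.03)
})

test_that("promoter planting yields one exact motif occurrence per gene", {
  pr <- generate_promoters(sprintf("g%02d", 1:20), rep(TRUE, 20),
                           "AGTCAAAC", 200L, seed = 3)
  expect_true(all(scan_iupac(pr$promoters, "AGTCAAAC") >= 1L))
  expect_true(all(nchar(pr$promoters) == 200L))
  expect_error(generate_promoters("g1", TRUE, "AGTCAAAC", 4L, seed = 1),
               "longer than promoter")
  pr2 <- generate_promoters(sprintf("g%02d", 1:20), rep(TRUE, 20),
                            "AGTCAAAC", 200L, seed = 3)
  expect_identical(pr, pr2)
})

test_that("planted genes carry indels in the recorded region", {
  genes <- generate_gene_models(sprintf("g%02d", 1:30), seed = 8)
  ind <- generate_indels(genes, rep(TRUE, 30), 1000L, seed = 9,
                         background_rate = 0)
  expect_true(all(ind$truth$has_indel))
  flags <- genes_with_indels(genes, ind$indels, 1000L)
  hit <- flags$has_upstream | flags$has_genic | flags$has_downstream
  expect_true(all(hit))
})

test_that("recovery metrics follow their definitions", {
  sets <- data.frame(probeset_id = sprintf("S%02d", 1:40),
                     is_cip = rep(c(TRUE, FALSE), c(20, 20)),
                     quadrant = "none", stringsAsFactors = FALSE)
  called <- c(sprintf("S%02d", 1:18), "S30")
  r <- evaluate_recovery(called, sets)
  expect_equal(r$sensitivity, 0.90)
  expect_equal(r$fdr, 1 / 19)
  r0 <- evaluate_recovery(character(0), sets)
  expect_equal(r0$sensitivity, 0)
  expect_equal(r0$fdr, 0)
  r1 <- evaluate_recovery(sprintf("S%02d", 1:20), sets)
  expect_equal(r1$sensitivity, 1)
  expect_equal(r1$fdr, 0)
})

test_that("dataset writer emits every pipeline input as plain text", {
  dat <- simulate_dataset(sim_scenario(n_probesets = 10L, rng_seed = 2))
  dir <- withr::local_tempdir()
  write_dataset(dat, dir)
  m <- read_intensity_table(file.path(dir, "intensities.tsv"))
  expect_equal(m, dat$intensities, tolerance = 1e-10)
  expect_identical(read_probe_map(file.path(dir, "probe_map.tsv")), dat$map)
  expect_identical(read_gff3(file.path(dir, "genes.gff3")), dat$genes)
  expect_identical(read_fasta(file.path(dir, "promoters.fa")), dat$promoters)
})
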