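fake_records <- function(p) {
  # p: matrix with columns cultivar/treatment/interaction
  data.frame(probe_id = sprintf("p%03d", seq_len(nrow(p))),
             F_cultivar = 1, p_cultivar = p[, 1], q_cultivar = p[, 1],
             F_treatment = 1, p_treatment = p[, 2], q_treatment = p[, 2],
             F_interaction = 1, p_interaction = p[, 3],
             q_interaction = p[, 3], degenerate = FALSE,
             stringsAsFactors = FALSE)
}

test_that("probes fall in the exact Venn region of their significant effects", {
  p <- rbind(c(0.005, 0.005, 0.005),
             c(0.005, 0.5, 0.005),
             c(0.5, 0.5, 0.5),
             c(0.01, 0.5, 0.5))
  v <- venn_regions(fake_records(p), alpha = 0.01)
  expect_equal(unname(v["triple"]), 1L)
  expect_equal(unname(v["cultivar_interaction"]), 1L)
  expect_equal(unname(v["none"]), 1L)
  expect_equal(unname(v["cultivar_only"]), 1L)  # p = alpha is significant
  expect_equal(sum(v), nrow(p))
})

test_that("the >= 3 core probe rule gates CIP calls", {
  p <- matrix(0.5, nrow = 22, ncol = 3)
  p[1:3, ] <- 0.005                 # set 1: exactly 3 core probes
  p[12:13, ] <- 0.005               # set 2: only 2 core probes
  map <- data.frame(probe_id = sprintf("p%03d", 1:22),
                    probeset_id = rep(c("S1", "S2"), each = 11),
                    probe_index = rep(1:11, 2), stringsAsFactors = FALSE)
  cips <- call_cips(fake_records(p), map, alpha = 0.01, min_core_probes = 3L)
  expect_equal(cips$probeset_id, "S1")
  expect_equal(cips$n_core_probes, 3L)
  expect_equal(cips$n_probes_total, 11L)
  # significance for two effects only never yields a core probe
  p2 <- matrix(0.5, nrow = 11, ncol = 3)
  p2[1:5, 1:2] <- 0.001
  cips2 <- call_cips(fake_records(p2), map[1:11, ], alpha = 0.01)
  expect_equal(nrow(cips2), 0L)
  expect_error(call_cips(fake_records(p), map[1:10, ]), "absent from map")
})

test_that("CIP calls shrink monotonically in alpha and the core threshold", {
  set.seed(401)
  p <- matrix(runif(330)^3, ncol = 3)
  map <- data.frame(probe_id = sprintf("p%03d", 1:110),
                    probeset_id = rep(sprintf("S%02d", 1:10), each = 11),
                    probe_index = rep(1:11, 10), stringsAsFactors = FALSE)
  rec <- fake_records(p)
  n_prev <- Inf
  for (a in c(0.2, 0.05, 0.01, 0.001)) {
    n <- nrow(call_cips(rec, map, alpha = a))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (k in 1:5) {
    n <- nrow(call_cips(rec, map, alpha = 0.2, min_core_probes = k))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("quadrants follow the sign pair of the mean log2 deltas", {
  design <- make_design(1L)
  sig <- function(cells) {
    stats::setNames(2^rep(cells, each = 1), design$array_id)
  }
  # design order: A/control, A/treated, B/control, B/treated
  q1 <- classify_quadrant(sig(c(10, 12, 8, 9)), design)
  expect_equal(q1$quadrant, "prefA_up")
  expect_equal(q1$cultivar_delta, 2.5)
  expect_equal(q1$treatment_delta, 1.5)
  q2 <- classify_quadrant(sig(c(8, 6, 10, 9)), design)
  expect_equal(q2$quadrant, "prefB_down")
  expect_equal(q2$cultivar_delta, -2.5)
  expect_equal(q2$treatment_delta, -1.5)
  q3 <- classify_quadrant(sig(c(10, 10, 10, 10)), design)
  expect_equal(q3$quadrant, "unclassified")
})

test_that("quadrant deltas ignore array order and global log2 shifts", {
  design <- make_design(3L)
  set.seed(402)
  s <- stats::setNames(2^rnorm(12, 8), design$array_id)
  q0 <- classify_quadrant(s, design)
  perm <- sample(12)
  q1 <- classify_quadrant(s[perm], design)
  expect_equal(q1, q0)
  q2 <- classify_quadrant(s * 2^1.7, design)  # +1.7 on the log2 scale
  expect_equal(q2$cultivar_delta, q0$cultivar_delta, tolerance = 1e-12)
  expect_equal(q2$treatment_delta, q0$treatment_delta, tolerance = 1e-12)
})

test_that("quadrant summaries partition the called set", {
  cips <- data.frame(probeset_id = sprintf("S%d", 1:6),
                     quadrant = c("prefA_up", "prefA_up", "prefB_down",
                                  "prefA_down", "prefB_up", "unclassified"),
                     stringsAsFactors = FALSE)
  qs <- quadrant_summary(cips)
  expect_equal(sum(qs), 6L)
  expect_equal(unname(qs["prefA_up"]), 2L)
  empty <- quadrant_summary(cips[0, ])
  expect_true(all(empty == 0L))
})
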