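test_that("DP alignment handles the elementary cases", {
  res <- dp_align(matrix(1), gap = -0.6)
  expect_equal(res$pairs, cbind(0L, 0L), ignore_attr = TRUE)
  expect_equal(res$score, 1)

  res <- dp_align(rbind(c(1, 0), c(0, 1)), gap = -0.5)
  expect_equal(res$pairs, cbind(0:1, 0:1), ignore_attr = TRUE)
  expect_equal(res$score, 2)

  expect_error(dp_align(matrix(numeric(0), 0, 0), gap = 0), "empty")
  expect_error(dp_align(matrix(c(1, NA), 1, 2), gap = 0), "finite")
})

test_that("DP equals the exhaustive chain oracle on random matrices", {
  set.seed(20)
  for (case in 1:120) {
    n <- sample(1:6, 1)
    m <- sample(1:6, 1)
    s <- matrix(rnorm(n * m), n, m)
    for (gap in c(0, -0.6)) {
      got <- dp_align(s, gap)
      expect_equal(got$score, oracle_dp_score(s, gap), tolerance = 1e-12)
      # returned path must reproduce its own score under the gap accounting
      p <- got$pairs
      if (nrow(p) > 0) {
        expect_true(all(diff(p[, 1]) > 0) && all(diff(p[, 2]) > 0))
        resc <- sum(s[p + 1L]) +
          gap * sum(pmax(diff(p[, 1]) - 1, 0) + pmax(diff(p[, 2]) - 1, 0))
        expect_equal(resc, got$score, tolerance = 1e-12)
      } else {
        expect_equal(got$score, 0)
      }
    }
  }
})

test_that("DP score is monotone in the score matrix when gaps are free", {
  set.seed(21)
  for (case in 1:25) {
    s <- matrix(runif(30, 0.01, 1), 5, 6)
    base <- dp_align(s, 0)$score
    s2 <- s
    idx <- sample(length(s), 1)
    s2[idx] <- s2[idx] + runif(1, 0, 0.5)
    expect_gte(dp_align(s2, 0)$score, base - 1e-12)
  }
})

test_that("fragment paths expand to monotone residue alignments", {
  r <- assemble_initial_alignment(cbind(0L, 0L), 8)
  expect_equal(r[, 1], 0:7, ignore_attr = TRUE)
  expect_equal(r[, 2], 0:7, ignore_attr = TRUE)

  r <- assemble_initial_alignment(rbind(c(0L, 1L), c(1L, 2L)), 8)
  expect_equal(nrow(r), 16L)
  expect_equal(r[1, ], c(q = 0L, p = 8L))
  expect_equal(r[16, ], c(q = 15L, p = 23L))
  expect_true(all(diff(r[, 1]) > 0) && all(diff(r[, 2]) > 0))

  empty <- assemble_initial_alignment(matrix(integer(0), 0, 2), 8)
  expect_equal(nrow(empty), 0L)
})

test_that("d0 follows the TM-align length law with a 0.5 A floor", {
  expect_equal(tm_d0(15), 0.5)
  expect_equal(tm_d0(8), 0.5)
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(100), 3.65, tolerance = 0.01)
  expect_gt(tm_d0(200), tm_d0(100))
})

test_that("residue-level refinement is a fixed point on identical and rigid pairs", {
  h <- generate_helix(40)
  seed_pairs <- cbind(q = c(0L, 5L, 11L), p = c(0L, 5L, 11L))
  ref <- residue_level_align(seed_pairs, h, h)
  expect_equal(ref$pairs[, 1], 0:39, ignore_attr = TRUE)
  expect_equal(ref$pairs[, 2], 0:39, ignore_attr = TRUE)

  moved <- rigid_copy(h, seed = 2)
  ref2 <- residue_level_align(seed_pairs, h, moved)
  expect_equal(nrow(ref2$pairs), 40L)
  d <- sqrt(rowSums((apply_transform(
    qcp_rmsd(h$coords, moved$coords)$transform, h$coords) -
      moved$coords)^2))
  expect_lt(max(d), 1e-6)

  # idempotence: re-applying on the refined alignment is stable
  ref3 <- residue_level_align(ref$pairs, h, h)
  expect_equal(ref3$pairs, ref$pairs)

  expect_error(residue_level_align(seed_pairs[1:2, ], h, h), "seed too small")
})

test_that("refined path equals a DP oracle on the computed score matrix", {
  set.seed(22)
  q <- random_walk_trace(10, seed = 31)
  p <- perturb_trace(q, 0.4, seed = 32)
  seed_pairs <- cbind(0:9, 0:9)
  ref <- residue_level_align(seed_pairs, q, p)
  tr <- qcp_rmsd(q$coords, p$coords)$transform
  qt <- apply_transform(tr, q$coords)
  d0v <- tm_d0(10)
  s <- 1 / (1 + (as.matrix(stats::dist(rbind(qt, p$coords)))[1:10, 11:20] /
                   d0v)^2)
  expect_equal(dp_align(s, 0)$score, oracle_dp_score(s, 0),
               tolerance = 1e-9)
  expect_equal(ref$score, oracle_dp_score(s, 0), tolerance = 1e-9)
})
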