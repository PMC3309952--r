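make_frag_pair <- function(l = 32L, sigma = 0, seed = 1L) {
  q <- random_walk_trace(l, seed = seed)
  p <- if (sigma > 0) perturb_trace(q, sigma, seed + 100L) else q
  list(q = decompose_fragments(q), p = decompose_fragments(p))
}

test_that("matched-pair retrieval honours the threshold and its domain", {
  fr <- make_frag_pair(32L)
  m <- fragment_score_matrix(fr$q, fr$p)
  pairs <- find_matched_pairs(m, 0.999)
  # identical proteins: the full diagonal must be present
  diag_rows <- pairs[pairs[, 1L] == pairs[, 2L], , drop = FALSE]
  expect_equal(sort(diag_rows[, 1L]), 0:3)
  # row-major ordering
  expect_true(all(diff(pairs[, 1L] * ncol(m) + pairs[, 2L]) > 0))
  expect_error(find_matched_pairs(m, 1 + 1e-9), "tau_f")
  expect_error(find_matched_pairs(m, 1 - pi), "tau_f")
  # an empty result is a valid contract
  low <- matrix(-0.5, 2, 2)
  expect_equal(nrow(find_matched_pairs(low, 0.9)), 0L)
})

test_that("MFS construction groups compatible pairs around anchors", {
  fr <- make_frag_pair(32L)
  m <- fragment_score_matrix(fr$q, fr$p)
  pairs <- find_matched_pairs(m, 0.999)
  diag_pairs <- pairs[pairs[, 1L] == pairs[, 2L], , drop = FALSE]
  mfs <- build_mfs(diag_pairs, fr$q, fr$p, eps_d = 2.0)
  full <- Filter(function(x) x$n_q == 4L && x$n_p == 4L, mfs)
  expect_length(full, 1L)
  expect_equal(full[[1L]]$f_q, 0:3)
  expect_equal(full[[1L]]$f_p, 0:3)
})

test_that("incompatible centroid distances exclude pairs from an anchor's MFS", {
  # synthetic centroid geometry: fragments on a line, but protein P has
  # fragment 2 displaced far away so the (0,0)-(2,2) anchor fails
  line_frag <- function(center) {
    list(coords = sweep(generate_helix(8)$coords, 2,
                        -c(center, 0, 0)),
         features = fragment_features(generate_helix(8)$coords))
  }
  fq <- lapply(c(0, 20, 40), line_frag)
  fp <- lapply(c(0, 20, 140), line_frag)  # third centroid 100 A off
  pairs <- cbind(0:2, 0:2)
  mfs <- build_mfs(pairs, fq, fp, eps_d = 2.0)
  sizes <- vapply(mfs, function(x) x$n_q, integer(1))
  expect_true(all(sizes <= 2L))
  expect_true(any(vapply(mfs, function(x) {
    identical(x$f_q, 0:1) && identical(x$f_p, 0:1)
  }, logical(1))))

  # brute-force oracle over all anchor/member combinations
  brute <- list()
  cq <- t(vapply(fq, function(f) colMeans(f$coords), numeric(3)))
  cp <- t(vapply(fp, function(f) colMeans(f$coords), numeric(3)))
  compat <- function(a, b) {
    (sign(pairs[a, 1] - pairs[b, 1]) == sign(pairs[a, 2] - pairs[b, 2])) &&
      pairs[a, 1] != pairs[b, 1] && pairs[a, 2] != pairs[b, 2] &&
      abs(sqrt(sum((cq[pairs[a, 1] + 1, ] - cq[pairs[b, 1] + 1, ])^2)) -
            sqrt(sum((cp[pairs[a, 2] + 1, ] - cp[pairs[b, 2] + 1, ])^2))) <= 2.0
  }
  for (a in 1:2) {
    for (b in (a + 1):3) {
      if (!compat(a, b)) next
      mem <- Filter(function(x) x == a || x == b ||
                      (compat(x, a) && compat(x, b)), 1:3)
      brute[[length(brute) + 1L]] <-
        list(f_q = sort(unique(pairs[mem, 1])),
             f_p = sort(unique(pairs[mem, 2])))
    }
  }
  expect_equal(length(mfs), length(unique(lapply(brute, function(x) x))))
  for (b in brute) {
    expect_true(any(vapply(mfs, function(x) {
      identical(x$f_q, as.integer(b$f_q)) && identical(x$f_p, as.integer(b$f_p))
    }, logical(1))))
  }
})

test_that("MFS score follows the three-term weighted formula", {
  m <- list(f_q = 0:3, f_p = 0:1, n_q = 4L, n_p = 2L)
  expect_equal(score_mfs(m, 10, 10, c(1, 1, 1) / 3),
               (0.4 + 0.2 + 0.5) / 3, tolerance = 1e-12)
  full <- list(f_q = 0:9, f_p = 0:9, n_q = 10L, n_p = 10L)
  expect_equal(score_mfs(full, 10, 10, c(1, 1, 1) / 3), 1.0)
  one_term <- list(f_q = 0:4, f_p = 0:7, n_q = 5L, n_p = 8L)
  expect_equal(score_mfs(one_term, 10, 99, c(1, 0, 0)), 0.5)
  expect_error(score_mfs(m, 0, 10), ">= 1")
})

test_that("redundancy filter keeps best and preserves disjoint sets", {
  a <- list(f_q = 0:3, f_p = 0:3, n_q = 4L, n_p = 4L, score = 0.9)
  a2 <- a
  a2$score <- 0.5
  b <- list(f_q = 5:7, f_p = 5:7, n_q = 3L, n_p = 3L, score = 0.4)
  kept <- filter_redundant_mfs(list(a2, a, b), 0.7)
  expect_length(kept, 2L)
  expect_equal(kept[[1L]]$score, 0.9)
  expect_equal(kept[[2L]]$score, 0.4)

  # brute-force greedy oracle on three overlapping sets
  s1 <- list(f_q = 0:4, f_p = 0:4, n_q = 5L, n_p = 5L, score = 0.8)
  s2 <- list(f_q = 0:3, f_p = 0:4, n_q = 4L, n_p = 5L, score = 0.7)  # jaccard 9/10
  s3 <- list(f_q = c(0L, 6L), f_p = c(0L, 6L), n_q = 2L, n_p = 2L,
             score = 0.6)  # jaccard 2/12 with s1
  kept <- filter_redundant_mfs(list(s3, s1, s2), 0.7)
  expect_equal(vapply(kept, `[[`, numeric(1), "score"), c(0.8, 0.6))
})

test_that("seed selection ranks, truncates, breaks ties, and falls back", {
  fr <- make_frag_pair(80L)
  fb <- select_seeds(list(), 20L, fr$q, fr$p[1:8])
  expect_length(fb, 1L)
  expect_equal(fb[[1L]]$n_q, 10L)
  expect_equal(fb[[1L]]$n_p, 8L)

  mk <- function(fq, fp, score) {
    list(f_q = fq, f_p = fp, n_q = length(fq), n_p = length(fp),
         score = score)
  }
  many <- lapply(seq(0.99, 0.70, length.out = 30), function(s) {
    mk(0:1, 0:1, s)
  })
  expect_length(select_seeds(many, 20L, fr$q, fr$p), 20L)
  tied <- list(mk(2:3, 0:1, 0.5), mk(0:1, 4:5, 0.5), mk(0:1, 2:3, 0.5))
  sel <- select_seeds(tied, 3L, fr$q, fr$p)
  expect_equal(sel[[1L]]$f_q, 0:1)
  expect_equal(sel[[1L]]$f_p, 2:3)
  expect_equal(sel[[3L]]$f_q, 2:3)
})

test_that("identical proteins yield a top seed with full coverage and maximal score", {
  q <- random_walk_trace(64L, seed = 9)
  frags <- decompose_fragments(q)
  seeds <- fragalign:::generate_seeds(frags, frags,
                                      align_params(tau_f = 0.9))
  top <- seeds[[1L]]
  expect_equal(top$f_q, 0:7)
  expect_equal(top$f_p, 0:7)
  expect_equal(top$score, 1.0, tolerance = 1e-9)
  for (s in seeds) {
    expect_gt(s$n_q, 0L)
    expect_gt(s$n_p, 0L)
    expect_true(all(diff(s$f_q) > 0))
    expect_true(all(diff(s$f_p) > 0))
  }
})
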