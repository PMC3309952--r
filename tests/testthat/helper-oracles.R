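# Independent oracles used across the suite.

# Best monotone match-chain score with linear gap accounting: backward
# recursion over all match-cell-to-match-cell transitions.  Independent of
# the package's grid recurrence; end gaps are free, internal skipped
# rows/columns each cost `gap`, and the empty chain scores 0.
oracle_dp_score <- function(s, gap) {
  n <- nrow(s)
  m <- ncol(s)
  best <- matrix(0, n, m)
  for (i in n:1) {
    for (j in m:1) {
      ext <- 0
      if (i < n && j < m) {
        for (k in (i + 1):n) {
          for (l in (j + 1):m) {
            cand <- gap * ((k - i - 1) + (l - j - 1)) + best[k, l]
            if (cand > ext) ext <- cand
          }
        }
      }
      best[i, j] <- s[i, j] + ext
    }
  }
  max(0, max(best))
}

# Scripted re-implementation of the superpose-and-extend window loop,
# using the Kabsch engine so the trajectory check is independent of QCP.
oracle_refine_window <- function(window, pairs, trace_q, trace_p,
                                 cutoff = 4.0, n_ms = 4L) {
  xq <- trace_q$coords[pairs[, 1L] + 1L, , drop = FALSE]
  xp <- trace_p$coords[pairs[, 2L] + 1L, , drop = FALSE]
  members <- window
  d <- NULL
  for (it in seq_len(n_ms)) {
    tr <- kabsch_rmsd(xq[members, , drop = FALSE],
                      xp[members, , drop = FALSE])$transform
    d <- sqrt(rowSums((apply_transform(tr, xq) - xp)^2))
    nm <- sort(unique(c(window, which(d < cutoff))))
    if (identical(nm, members)) break
    members <- nm
  }
  list(members = members, distances = d)
}

# uniform random proper rotation
random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
         3, 3, byrow = TRUE)
}

random_rigid <- function() {
  rigid_transform(random_rotation(), stats::runif(3, -20, 20))
}

# monotone random residue alignment between two traces
random_alignment <- function(n_pairs, l_q, l_p) {
  cbind(q = sort(sample.int(l_q, n_pairs)) - 1L,
        p = sort(sample.int(l_p, n_pairs)) - 1L)
}
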