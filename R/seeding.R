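#' Matched fragment pairs above a similarity threshold
#'
#' @param score_matrix Fragment score matrix from
#'   [fragment_score_matrix()].
#' @param tau_f Similarity threshold, in `(1 - pi, 1]`.
#' @return Integer matrix with columns `i`, `j` (0-based fragment indices)
#'   in row-major order; zero rows when nothing matches.
#' @export
find_matched_pairs <- function(score_matrix, tau_f) {
  if (!(tau_f > 1 - pi && tau_f <= 1)) {
    stop("tau_f must lie in (1 - pi, 1]")
  }
  hits <- which(t(score_matrix) >= tau_f)  # transpose => row-major order
  m <- ncol(score_matrix)
  i <- (hits - 1L) %/% m
  j <- (hits - 1L) %% m
  cbind(i = i, j = j)
}

fragment_centroids <- function(frags) {
  do.call(rbind, lapply(frags, function(f) colMeans(f$coords)))
}

new_mfs <- function(f_q, f_p, score = NA_real_) {
  f_q <- sort(unique(as.integer(f_q)))
  f_p <- sort(unique(as.integer(f_p)))
  if (length(f_q) == 0L || length(f_p) == 0L) {
    stop("a matched fragment set needs two non-empty subsets")
  }
  list(f_q = f_q, f_p = f_p,
       n_q = length(f_q), n_p = length(f_p), score = score)
}

#' Build matched fragment sets from matched pairs
#'
#' Every order-consistent anchor pair of matched fragment pairs whose
#' fragment-centroid distances agree within `eps_d` spawns one candidate
#' MFS: the set of all matched pairs compatible (same order and
#' centroid-distance test) with both anchor members.  Duplicate sets are
#' collapsed.
#'
#' @param matched_pairs Output of [find_matched_pairs()].
#' @param frags_q,frags_p Fragment lists of target and database protein.
#' @param eps_d Centroid-distance tolerance, Angstrom (> 0).
#' @return List of matched fragment sets (possibly empty), each with
#'   fields `f_q`, `f_p` (0-based, strictly increasing), `n_q`, `n_p`,
#'   `score` (unset).
#' @export
build_mfs <- function(matched_pairs, frags_q, frags_p, eps_d) {
  stopifnot(eps_d > 0)
  n <- NROW(matched_pairs)
  if (n < 2L) return(list())
  i <- matched_pairs[, 1L]
  j <- matched_pairs[, 2L]
  dq <- as.matrix(stats::dist(fragment_centroids(frags_q)))
  dp <- as.matrix(stats::dist(fragment_centroids(frags_p)))
  di <- outer(i, i, "-")
  dj <- outer(j, j, "-")
  compat <- (sign(di) == sign(dj)) & di != 0L & dj != 0L &
    abs(dq[cbind(rep(i + 1L, n), rep(i + 1L, each = n))] -
          dp[cbind(rep(j + 1L, n), rep(j + 1L, each = n))]) <= eps_d
  dim(compat) <- c(n, n)
  diag(compat) <- TRUE

  seen <- new.env(parent = emptyenv())
  out <- list()
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      if (!compat[a, b]) next
      members <- which(compat[, a] & compat[, b])
      mfs <- new_mfs(i[members], j[members])
      key <- paste(c(mfs$f_q, NA, mfs$f_p), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- mfs
      }
    }
  }
  out
}

#' Score a matched fragment set
#'
#' `S_MFS = w1 N_Q / N_f^Q + w2 N_P / N_f^P +
#'  w3 min(N_Q, N_P) / max(N_Q, N_P)`: coverage of both proteins plus a
#' balance term favouring sets of comparable cardinality.
#'
#' @param mfs A matched fragment set.
#' @param n_f_q,n_f_p Total fragment counts of target and database
#'   protein (>= 1).
#' @param w Length-3 non-negative weights.
#' @return The score, in `(0, sum(w)]`.
#' @examples
#' m <- list(f_q = 0:3, f_p = 0:1, n_q = 4, n_p = 2)
#' score_mfs(m, 10, 10, c(1, 1, 1) / 3)  # ~0.3667
#' @export
score_mfs <- function(mfs, n_f_q, n_f_p, w = c(1, 1, 1) / 3) {
  if (n_f_q < 1L || n_f_p < 1L) stop("fragment counts must be >= 1")
  stopifnot(length(w) == 3L, all(w >= 0))
  w[1L] * mfs$n_q / n_f_q + w[2L] * mfs$n_p / n_f_p +
    w[3L] * min(mfs$n_q, mfs$n_p) / max(mfs$n_q, mfs$n_p)
}

mfs_member_tags <- function(mfs) {
  c(paste0("q", mfs$f_q), paste0("p", mfs$f_p))
}

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

order_mfs <- function(mfs_list) {
  scores <- vapply(mfs_list, `[[`, numeric(1), "score")
  fq1 <- vapply(mfs_list, function(m) m$f_q[1L], numeric(1))
  fp1 <- vapply(mfs_list, function(m) m$f_p[1L], numeric(1))
  order(-scores, fq1, fp1)
}

#' Drop redundant matched fragment sets
#'
#' Greedy keep-best by score: an MFS is removed when the Jaccard index of
#' its combined fragment member set (target and database fragments tagged
#' separately) with an already kept MFS reaches the threshold.
#'
#' @param mfs_list Scored MFS list.
#' @param jaccard_threshold In `(0, 1]`.
#' @return The surviving MFS list, best first.
#' @export
filter_redundant_mfs <- function(mfs_list, jaccard_threshold = 0.7) {
  stopifnot(jaccard_threshold > 0, jaccard_threshold <= 1)
  if (length(mfs_list) <= 1L) return(mfs_list)
  mfs_list <- mfs_list[order_mfs(mfs_list)]
  kept <- list()
  kept_tags <- list()
  for (m in mfs_list) {
    tags <- mfs_member_tags(m)
    redundant <- any(vapply(kept_tags, function(t) {
      jaccard(tags, t) >= jaccard_threshold
    }, logical(1)))
    if (!redundant) {
      kept[[length(kept) + 1L]] <- m
      kept_tags[[length(kept_tags) + 1L]] <- tags
    }
  }
  kept
}

#' Select the top seed matched fragment sets
#'
#' Sorts by descending score (ties: smaller first target fragment index,
#' then smaller first database fragment index) and keeps at most
#' `n_seed`.  An empty candidate list falls back to the single MFS
#' containing every fragment of both proteins, so a seed always exists.
#'
#' @param mfs_list Scored MFS list (possibly empty).
#' @param n_seed Maximum number of seeds (>= 1).
#' @param frags_q,frags_p Fragment lists (used for the fallback seed).
#' @param w MFS score weights (used to score the fallback seed).
#' @return List of 1..`n_seed` matched fragment sets, best first.
#' @export
select_seeds <- function(mfs_list, n_seed, frags_q, frags_p,
                         w = c(1, 1, 1) / 3) {
  stopifnot(n_seed >= 1L)
  if (length(mfs_list) == 0L) {
    fb <- new_mfs(seq_along(frags_q) - 1L, seq_along(frags_p) - 1L)
    fb$score <- score_mfs(fb, length(frags_q), length(frags_p), w)
    return(list(fb))
  }
  mfs_list <- mfs_list[order_mfs(mfs_list)]
  mfs_list[seq_len(min(n_seed, length(mfs_list)))]
}

# Full seeding stage: match fragments, anchor-grow MFS candidates, score,
# de-duplicate and rank.  The anchor enumeration is capped at the
# params$max_anchor_pairs best-scoring matched pairs.
generate_seeds <- function(frags_q, frags_p, params = align_params(),
                           score_matrix = NULL) {
  smat <- if (is.null(score_matrix)) fragment_score_matrix(frags_q, frags_p)
          else score_matrix
  pairs <- find_matched_pairs(smat, params$tau_f)
  if (NROW(pairs) > params$max_anchor_pairs) {
    sc <- smat[pairs + 1L]
    keep <- order(-sc)[seq_len(params$max_anchor_pairs)]
    pairs <- pairs[sort(keep), , drop = FALSE]
  }
  mfs_list <- build_mfs(pairs, frags_q, frags_p, params$eps_d)
  mfs_list <- lapply(mfs_list, function(m) {
    m$score <- score_mfs(m, length(frags_q), length(frags_p), params$w)
    m
  })
  mfs_list <- filter_redundant_mfs(mfs_list, params$jaccard_threshold)
  select_seeds(mfs_list, params$n_seed, frags_q, frags_p, params$w)
}
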