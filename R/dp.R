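#' Dynamic-programming alignment with traceback
#'
#' Alignment over a score matrix with a linear gap penalty and free end
#' gaps: the boundary row/column is initialized to 0, a match may open a
#' fresh path (so residues before the first and after the last aligned
#' pair are unpenalized in both chains), and the traceback starts at the
#' best-scoring cell of the matrix.  Only gaps between matched pairs pay
#' the penalty.  Tie-breaking is deterministic: diagonal > up > left.
#' The empty path (score 0) is returned when no path scores positively.
#'
#' @param s Finite numeric score matrix (n x m, n, m >= 1).
#' @param gap Gap penalty added per skipped row/column inside the path
#'   (<= 0 normally; 0 for the residue-level stage).
#' @return List with `pairs` (k x 2 integer matrix of 0-based matched
#'   row/column indices, strictly increasing in both columns) and
#'   `score`.
#' @examples
#' dp_align(diag(2), gap = -0.5)$score  # 2
#' @export
dp_align <- function(s, gap) {
  s <- as.matrix(s)
  if (length(s) == 0L) stop("empty score matrix")
  if (!all(is.finite(s))) stop("score matrix must be finite")
  storage.mode(s) <- "double"
  res <- dp_fill_traceback(s, gap)
  list(pairs = res$pairs, score = res$score)
}

#' Expand a fragment-level path into a residue alignment
#'
#' Each aligned fragment pair (i, j) contributes the residue pairs
#' `(i l_f + t, j l_f + t)` for `t = 0..l_f - 1`; concatenating along the
#' path preserves strict monotonicity because fragment indices increase
#' along it.
#'
#' @param path k x 2 matrix of 0-based aligned fragment indices (a
#'   [dp_align()] `pairs` matrix at fragment level).
#' @param l_f Fragment length, residues.
#' @return Integer matrix of 0-based residue pairs (possibly 0 rows).
#' @examples
#' assemble_initial_alignment(cbind(0L, 1L), 8)[1, ]  # (0, 8)
#' @export
assemble_initial_alignment <- function(path, l_f = 8L) {
  l_f <- as.integer(l_f)
  if (NROW(path) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("q", "p"))))
  }
  t_off <- seq_len(l_f) - 1L
  q <- as.integer(rep(path[, 1L] * l_f, each = l_f) + t_off)
  p <- as.integer(rep(path[, 2L] * l_f, each = l_f) + t_off)
  cbind(q = q, p = p)
}

#' TM-score distance scale d0
#'
#' `d0(L) = max(1.24 (L - 15)^(1/3) - 1.8, d0_min)`; the floor applies for
#' all short chains (L <= 15 in particular).
#'
#' @param l Residue count used for normalization (>= 1).
#' @param d0_min Floor, Angstrom.
#' @return d0 in Angstrom.
#' @examples
#' tm_d0(100)  # about 3.65
#' @export
tm_d0 <- function(l, d0_min = 0.5) {
  stopifnot(l >= 1)
  if (l <= 15) return(d0_min)
  max(1.24 * (l - 15)^(1 / 3) - 1.8, d0_min)
}

# TM-align style residue score matrix between transformed target
# coordinates and database coordinates: 1 / (1 + (d_ij / d0)^2)
residue_score_matrix <- function(qt, p, d0_val) {
  d2 <- outer(rowSums(qt^2), rowSums(p^2), "+") - 2 * tcrossprod(qt, p)
  d2[d2 < 0] <- 0
  # quantized at 1e-9 so tie-breaking is stable against frame noise
  round(1 / (1 + d2 / d0_val^2), 9)
}

#' Residue-level alignment refinement
#'
#' Superimposes the target over the database protein with the optimal
#' (QCP) transform of the current alignment's paired coordinates, scores
#' every residue pair with the TM-align function
#' `S_r(i, j) = 1 / (1 + (d_ij / d0)^2)` (d0 taken at the shorter chain
#' length), and re-aligns all residues by dynamic programming with gap
#' penalty `g_r = 0`.
#'
#' @param pairs Current residue alignment: k x 2 matrix of 0-based index
#'   pairs, k >= 3.
#' @param trace_q,trace_p Target and database [ca_trace()]s.
#' @param params An [align_params()].
#' @return List with `pairs` (the refined alignment), `transform` (the
#'   seed transform used) and `score` (DP score).
#' @export
residue_level_align <- function(pairs, trace_q, trace_p,
                                params = align_params()) {
  if (NROW(pairs) < 3L) stop("seed too small: need >= 3 residue pairs")
  xq <- trace_q$coords[pairs[, 1L] + 1L, , drop = FALSE]
  xp <- trace_p$coords[pairs[, 2L] + 1L, , drop = FALSE]
  tr <- qcp_rmsd(xq, xp, want_rotation = TRUE)$transform
  qt <- apply_transform(tr, trace_q$coords)
  d0_val <- tm_d0(min(trace_q$length, trace_p$length), params$d0_min)
  s <- residue_score_matrix(qt, trace_p$coords, d0_val)
  res <- dp_align(s, params$g_r)
  list(pairs = res$pairs, transform = tr, score = res$score)
}
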