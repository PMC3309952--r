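#' Decompose a trace into non-overlapping backbone fragments
#'
#' Tiles the trace with fragments of `l_f` consecutive residues
#' (N- to C-terminus), giving `floor(L / l_f)` fragments; trailing
#' residues shorter than one fragment stay unfragmented but remain
#' alignable at residue level.  Each fragment carries its pairwise
#' C-alpha distance feature vector.
#'
#' @param trace A [ca_trace()].
#' @param l_f Fragment length, residues (default 8).
#' @return List of fragments; each has `source_id`, `index` (0-based),
#'   `start` (0-based residue index), `coords` (l_f x 3) and `features`
#'   (the `choose(l_f, 2)` pairwise distances).
#' @examples
#' frags <- decompose_fragments(generate_helix(20))
#' length(frags)  # 2
#' @export
decompose_fragments <- function(trace, l_f = 8L) {
  stopifnot(inherits(trace, "ca_trace"))
  l_f <- as.integer(l_f)
  if (trace$length < l_f) {
    stop("trace too short for fragments: L = ", trace$length, " < ", l_f)
  }
  n_f <- trace$length %/% l_f
  lapply(seq_len(n_f) - 1L, function(k) {
    idx <- k * l_f + seq_len(l_f)
    coords <- trace$coords[idx, , drop = FALSE]
    list(source_id = trace$id, index = k, start = k * l_f,
         coords = coords, features = fragment_features(coords))
  })
}

#' Pairwise-distance feature vector of a fragment
#'
#' All `choose(n, 2)` intra-fragment C-alpha distances in lexicographic
#' pair order (0,1), (0,2), ..., (n-2, n-1).  Distances are invariant to
#' rigid motion (and to reflection; chirality is resolved later by the
#' proper-rotation superposition).
#'
#' @param coords n x 3 fragment coordinates, Angstrom.
#' @return Numeric vector of `choose(n, 2)` strictly positive distances.
#' @examples
#' fragment_features(generate_helix(8)$coords)
#' @export
fragment_features <- function(coords) {
  coords <- as_coord_matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite fragment coordinates")
  d <- as.numeric(stats::dist(coords))
  if (any(d <= 0)) stop("degenerate fragment: coincident C-alpha positions")
  # stats::dist emits pairs (1,2),(1,3),...,(1,n),(2,3),... = lexicographic
  d
}

#' Fragment similarity: inverse-cosine feature score
#'
#' `s_f = 1 - arccos(<D_A, D_B> / (||D_A|| ||D_B||))` with the cosine
#' argument clamped to `[-1, 1]` against floating-point overshoot.
#' Identical (parallel) feature vectors score 1; the minimum is `1 - pi`.
#'
#' @param d_a,d_b Feature vectors of equal length.
#' @return Scalar score in `[1 - pi, 1]`.
#' @examples
#' fragment_similarity(c(1, 0), c(1, 1))  # 1 - pi/4
#' @export
fragment_similarity <- function(d_a, d_b) {
  na <- sqrt(sum(d_a^2))
  nb <- sqrt(sum(d_b^2))
  if (na == 0 || nb == 0) stop("degenerate feature: zero norm")
  cosv <- sum(d_a * d_b) / (na * nb)
  # quantizing the cosine before acos keeps the score invariant under
  # rigid motion: acos amplifies 1e-15 rounding noise near cos = 1 to
  # 1e-8 in the angle, which would destabilize tie-breaking downstream
  cosv <- round(min(1, max(-1, cosv)), 9)
  1 - acos(cosv)
}

#' All-against-all fragment score matrix
#'
#' Entry (i, j) is [fragment_similarity()] of fragment i of the target and
#' fragment j of the database protein; computed by a single normalized
#' cross-product for speed.
#'
#' @param frags_q,frags_p Fragment lists from [decompose_fragments()].
#' @return Numeric `length(frags_q)` x `length(frags_p)` matrix.
#' @export
fragment_score_matrix <- function(frags_q, frags_p) {
  if (length(frags_q) == 0L || length(frags_p) == 0L)
    stop("fragment lists must be non-empty")
  fq <- do.call(rbind, lapply(frags_q, `[[`, "features"))
  fp <- do.call(rbind, lapply(frags_p, `[[`, "features"))
  fq <- fq / sqrt(rowSums(fq^2))
  fp <- fp / sqrt(rowSums(fp^2))
  cosm <- tcrossprod(fq, fp)
  cosm[cosm > 1] <- 1
  cosm[cosm < -1] <- -1
  # same cosine quantization as fragment_similarity()
  1 - acos(round(cosm, 9))
}
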