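#' Sliding seed windows over a residue alignment
#'
#' Exactly `L_R - L_W + 1` contiguous windows; when the alignment is
#' shorter than the window the whole alignment is returned as the single
#' (degenerate) window.
#'
#' @param n_pairs Alignment length `L_R`.
#' @param l_w Window length (>= 3).
#' @return List of integer index vectors (1-based positions into the
#'   alignment).
#' @examples
#' length(generate_windows(10, 4))  # 7
#' @export
generate_windows <- function(n_pairs, l_w) {
  stopifnot(l_w >= 3L)
  if (n_pairs < l_w) {
    return(list(seq_len(n_pairs)))
  }
  lapply(0:(n_pairs - l_w), function(s) s + seq_len(l_w))
}

#' Superpose-and-extend refinement of one window
#'
#' Iterates up to `n_ms` times: superpose the window members optimally
#' (QCP), then reset membership to the seed window plus every alignment
#' pair whose post-superposition distance is strictly below the cutoff.
#' Stops early when membership stabilizes.
#'
#' @param window Integer vector of 1-based positions into the alignment
#'   (the seed window, >= 3 pairs).
#' @param pairs Full residue alignment (k x 2, 0-based).
#' @param trace_q,trace_p The aligned [ca_trace()]s.
#' @param cutoff Distance cutoff, Angstrom (strict `<`).
#' @param n_ms Maximum iterations.
#' @return List with `members` (1-based positions into the alignment),
#'   `transform`, and `distances` (per-pair distances of the whole
#'   alignment under the final transform); `NULL` if the window geometry
#'   is degenerate.
#' @export
refine_window <- function(window, pairs, trace_q, trace_p,
                          cutoff = 4.0, n_ms = 4L) {
  if (length(window) < 3L) stop("window must hold at least 3 pairs")
  xq <- trace_q$coords[pairs[, 1L] + 1L, , drop = FALSE]
  xp <- trace_p$coords[pairs[, 2L] + 1L, , drop = FALSE]
  members <- window
  tr <- NULL
  d <- NULL
  for (it in seq_len(n_ms)) {
    tr <- tryCatch(
      qcp_rmsd(xq[members, , drop = FALSE], xp[members, , drop = FALSE],
               want_rotation = TRUE)$transform,
      error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    qt <- apply_transform(tr, xq)
    d <- sqrt(rowSums((qt - xp)^2))
    new_members <- sort(unique(c(window, which(d < cutoff))))
    if (identical(new_members, members)) break
    members <- new_members
  }
  list(members = members, transform = tr, distances = d)
}

#' TM-score of a set of aligned distances
#'
#' `S_a = (1 / L_norm) * sum 1 / (1 + (d_i / d0)^2)` over the aligned
#' pairs; 1 for a full-length zero-distance alignment, 0 for an empty
#' one.
#'
#' @param distances Post-superposition distances of the aligned pairs,
#'   Angstrom.
#' @param l_norm Normalization length (>= 1), conventionally the shorter
#'   chain length.
#' @param d0_val Distance scale from [tm_d0()].
#' @return Score in `[0, 1]`.
#' @examples
#' tm_score(c(0, 0), 2, 1)  # 1
#' @export
tm_score <- function(distances, l_norm, d0_val) {
  stopifnot(l_norm >= 1)
  if (length(distances) == 0L) return(0)
  sum(1 / (1 + (distances / d0_val)^2)) / l_norm
}

#' Maximal-subset alignment search
#'
#' MaxSub-style search: every window of the alignment is refined with
#' [refine_window()]; the refined member set with the largest TM-score
#' (normalized by the shorter chain length) becomes the maximal subset M.
#' Its transform then superimposes the whole target, and the next-round
#' alignment is rebuilt from the residue-level DP path restricted to
#' pairs strictly closer than the cutoff, which preserves the ordered
#' (non-crossing) alignment invariant.
#'
#' @param pairs Residue alignment (k x 2, 0-based, k >= 3).
#' @param trace_q,trace_p The aligned [ca_trace()]s.
#' @param params An [align_params()].
#' @return List with `members` (M as 1-based positions into `pairs`),
#'   `transform`, `tm` (the winning TM-score), `pairs_next` (the new
#'   alignment) and `degenerate` flag (TRUE when every window failed, in
#'   which case the input alignment is returned unchanged).
#' @export
max_subset <- function(pairs, trace_q, trace_p, params = align_params()) {
  if (NROW(pairs) < 3L) stop("alignment too small for maximal-subset search")
  l_norm <- min(trace_q$length, trace_p$length)
  d0_val <- tm_d0(l_norm, params$d0_min)
  windows <- generate_windows(NROW(pairs), params$l_w)

  best <- NULL
  best_tm <- -Inf
  best_size <- -1L
  best_start <- Inf
  for (k in seq_along(windows)) {
    ref <- refine_window(windows[[k]], pairs, trace_q, trace_p,
                         cutoff = params$cutoff, n_ms = params$n_ms)
    if (is.null(ref)) next
    tm <- tm_score(ref$distances[ref$members], l_norm, d0_val)
    start <- windows[[k]][1L]
    if (tm > best_tm ||
        (tm == best_tm && (length(ref$members) > best_size ||
                           (length(ref$members) == best_size &&
                            start < best_start)))) {
      best <- ref
      best_tm <- tm
      best_size <- length(ref$members)
      best_start <- start
    }
  }
  if (is.null(best)) {
    warning("all windows degenerate; alignment left unchanged")
    return(list(members = seq_len(NROW(pairs)),
                transform = NULL, tm = NA_real_,
                pairs_next = pairs, degenerate = TRUE))
  }
  # rebuild the next-round alignment through the residue-level DP so the
  # ordered-set invariant holds, keeping only pairs inside the cutoff
  qt <- apply_transform(best$transform, trace_q$coords)
  s <- residue_score_matrix(qt, trace_p$coords, d0_val)
  path <- dp_align(s, params$g_r)$pairs
  if (NROW(path) > 0L) {
    d <- sqrt(rowSums((qt[path[, 1L] + 1L, , drop = FALSE] -
                         trace_p$coords[path[, 2L] + 1L, , drop = FALSE])^2))
    path <- path[d < params$cutoff, , drop = FALSE]
  }
  list(members = best$members, transform = best$transform, tm = best_tm,
       pairs_next = path, degenerate = FALSE)
}
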