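#' Pipeline parameters
#'
#' Collects every tunable of the alignment pipeline with its default.
#' Defaults follow the method's stated settings where given (`l_f = 8`
#' residue fragments, residue-level gap penalty `g_r = 0`, 4.0 Angstrom
#' distance cutoff, `n_iter = 3`, `n_seed = 20`) and otherwise use
#' documented package choices.
#'
#' @param n_iter Refinement rounds of the residue-level / maximal-subset
#'   loop (>= 1).
#' @param n_seed Maximum number of seed matched fragment sets carried into
#'   alignment (>= 1).
#' @param l_f Fragment length in residues (fixed at 8 by the method; kept
#'   as a parameter for transparency).
#' @param tau_f Fragment similarity threshold for matched pairs, in the
#'   range (1 - pi, 1].
#' @param eps_d Centroid-distance compatibility tolerance for matched-pair
#'   anchors, Angstrom (> 0).
#' @param jaccard_threshold Redundancy threshold for MFS and per-round
#'   alignment filtering, in (0, 1].
#' @param w Length-3 non-negative weights of the MFS scoring function.
#' @param g_f Fragment-level gap penalty (<= 0).
#' @param g_r Residue-level gap penalty (0 by construction of the method).
#' @param l_w MaxSub seed window length (>= 3).
#' @param n_ms Iterations of the superpose-and-extend loop per window.
#' @param cutoff Distance cutoff in Angstrom for subset extension, final
#'   pair selection and PSI (strict `<`).
#' @param d0_min Floor for the TM-score distance scale d0, Angstrom.
#' @param max_anchor_pairs Cap on the number of best-scoring matched
#'   fragment pairs enumerated as MFS anchors.
#'
#' @return An object of class `"align_params"` (a validated list).
#' @examples
#' p <- align_params(n_iter = 5)
#' p$n_iter
#' @export
align_params <- function(n_iter = 3L,
                         n_seed = 20L,
                         l_f = 8L,
                         tau_f = 0.8,
                         eps_d = 2.0,
                         jaccard_threshold = 0.7,
                         w = c(1, 1, 1) / 3,
                         g_f = -0.6,
                         g_r = 0,
                         l_w = 4L,
                         n_ms = 4L,
                         cutoff = 4.0,
                         d0_min = 0.5,
                         max_anchor_pairs = 200L) {
  p <- list(n_iter = as.integer(n_iter), n_seed = as.integer(n_seed),
            l_f = as.integer(l_f), tau_f = tau_f, eps_d = eps_d,
            jaccard_threshold = jaccard_threshold, w = as.numeric(w),
            g_f = g_f, g_r = g_r, l_w = as.integer(l_w),
            n_ms = as.integer(n_ms), cutoff = cutoff, d0_min = d0_min,
            max_anchor_pairs = as.integer(max_anchor_pairs))
  stopifnot(p$n_iter >= 1L, p$n_seed >= 1L, p$l_f >= 2L,
            p$tau_f > 1 - pi, p$tau_f <= 1,
            p$eps_d > 0,
            p$jaccard_threshold > 0, p$jaccard_threshold <= 1,
            length(p$w) == 3L, all(p$w >= 0),
            p$g_f <= 0,
            p$l_w >= 3L, p$n_ms >= 1L,
            p$cutoff > 0, p$d0_min > 0,
            p$max_anchor_pairs >= 1L)
  class(p) <- "align_params"
  p
}

#' @export
print.align_params <- function(x, ...) {
  cat("Alignment pipeline parameters:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
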