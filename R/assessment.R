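#' Percentage of structural similarity (PSI)
#'
#' Share of aligned residue pairs whose post-superposition distance is
#' strictly below the cutoff, expressed as a percentage of the shorter
#' chain length k = min(L_Q, L_P).  The chain-length denominator puts PSI
#' on the same scale as the fitted null mean `mu_PSI(k)` used by the
#' z-score.
#'
#' @param pairs Residue alignment (k x 2, 0-based); may have zero rows.
#' @param trace_q,trace_p The aligned [ca_trace()]s.
#' @param transform The final [rigid_transform()].
#' @param cutoff Distance cutoff, Angstrom (strict `<`), default 4.0.
#' @return PSI in `[0, 100]`.
#' @export
psi_score <- function(pairs, trace_q, trace_p, transform, cutoff = 4.0) {
  k <- min(trace_q$length, trace_p$length)
  if (NROW(pairs) == 0L) return(0)
  d <- pair_distances(pairs, trace_q, trace_p, transform)
  100 * sum(d < cutoff) / k
}

#' Length-calibrated null parameters of PSI
#'
#' Fitted power laws for the mean and standard deviation of PSI between
#' unrelated structures at minimum chain length k:
#' `mu_PSI = 375.64 k^-0.5295`, `sigma_PSI = 99.67 k^-0.5885`.
#'
#' @param k Minimum chain length (>= 1).
#' @return `mu_psi(k)` / `sigma_psi(k)` in PSI units.
#' @name psi_null
NULL

#' @rdname psi_null
#' @export
mu_psi <- function(k) {
  stopifnot(k >= 1)
  375.64 * k^-0.5295
}

#' @rdname psi_null
#' @export
sigma_psi <- function(k) {
  stopifnot(k >= 1)
  99.67 * k^-0.5885
}

#' z-score of a PSI value
#'
#' `z = (PSI - mu_PSI(k)) / sigma_PSI(k)` with the fitted length-dependent
#' null of [mu_psi()] and [sigma_psi()].
#'
#' @param psi_value PSI percentage.
#' @param k Minimum chain length between the two proteins (>= 1).
#' @return The z-score.
#' @examples
#' psi_zscore(100, 100)  # about 10.1
#' @export
psi_zscore <- function(psi_value, k) {
  (psi_value - mu_psi(k)) / sigma_psi(k)
}

#' Length-normalized RMSD (RMSD100)
#'
#' `RMSD100 = cRMSD / (1 + ln(Ne / 100))`: the cRMSD expected if the
#' aligned structures were 100 residues long.  The denominator crosses
#' zero near Ne ~ 37, so callers flag alignments shorter than 37 pairs
#' and report raw cRMSD instead (see [align_structures()]).
#'
#' @param crmsd Coordinate RMSD over the aligned pairs, Angstrom (>= 0).
#' @param ne Number of aligned pairs (>= 37 for a stable value).
#' @return RMSD100 in Angstrom.
#' @examples
#' rmsd100(4, 200)  # about 2.363
#' @export
rmsd100 <- function(crmsd, ne) {
  stopifnot(ne >= 1, crmsd >= 0)
  denom <- 1 + log(ne / 100)
  if (denom <= 0) {
    stop("RMSD100 undefined for Ne < 37; report raw cRMSD instead")
  }
  crmsd / denom
}

# Assemble the final report fields from a best alignment and its working
# transform.  Short alignments (< 37 pairs) keep raw cRMSD in RMSD100's
# place and are flagged.
build_report <- function(trace_q, trace_p, pairs, transform, tm,
                         params, flags = character(0)) {
  k <- min(trace_q$length, trace_p$length)
  ne <- NROW(pairs)
  if (ne == 0L) {
    rep <- list(target_id = trace_q$id, db_id = trace_p$id,
                L_Q = trace_q$length, L_P = trace_p$length,
                Ne = 0L, cRMSD = NA_real_, RMSD100 = NA_real_,
                S_a = NA_real_, PSI = NA_real_, z = NA_real_,
                k = k, pairs = pairs, transform = NULL,
                flags = unique(c(flags, "no_alignment")))
    class(rep) <- "structaln"
    return(rep)
  }
  crmsd <- if (ne >= 3L) {
    qcp_rmsd(trace_q$coords[pairs[, 1L] + 1L, , drop = FALSE],
             trace_p$coords[pairs[, 2L] + 1L, , drop = FALSE],
             want_rotation = FALSE)$rmsd
  } else {
    mean(pair_distances(pairs, trace_q, trace_p, transform))
  }
  psi <- psi_score(pairs, trace_q, trace_p, transform, params$cutoff)
  if (ne >= 37L) {
    r100 <- rmsd100(crmsd, ne)
  } else {
    r100 <- crmsd
    flags <- c(flags, "short_alignment")
  }
  rep <- list(target_id = trace_q$id, db_id = trace_p$id,
              L_Q = trace_q$length, L_P = trace_p$length,
              Ne = ne, cRMSD = crmsd, RMSD100 = r100,
              S_a = tm, PSI = psi, z = psi_zscore(psi, k),
              k = k, pairs = pairs, transform = transform,
              flags = unique(flags))
  class(rep) <- "structaln"
  rep
}
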