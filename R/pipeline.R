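#' Align two protein structures
#'
#' The full alignment pipeline for one pair: (1) matched-fragment-set
#' seeding, (2) fragment-level DP assembly of each seed into an initial
#' residue alignment, (3) residue-level DP refinement under the QCP
#' superposition of the current alignment, (4) maximal-subset (MaxSub
#' style) search giving the subset TM-score and the next-round alignment
#' -- steps 3 and 4 repeated `n_iter` times with per-round redundancy
#' filtering and keep-best selection across seeds -- and (5) final
#' assessment (PSI, z-score, cRMSD, RMSD100) of the best alignment.
#' Deterministic for fixed inputs and parameters.
#'
#' Traces shorter than one fragment fall back to a residue-only seed
#' (flagged `"residue_only"`); a pair with no viable seed at all yields a
#' report with `Ne = 0` and flag `"no_alignment"`.
#'
#' @param trace_q Target structure, a [ca_trace()].
#' @param trace_p Database structure, a [ca_trace()].
#' @param params An [align_params()].
#' @return An object of class `"structaln"`: fields `target_id`, `db_id`,
#'   `L_Q`, `L_P`, `Ne`, `cRMSD`, `RMSD100`, `S_a` (TM-score), `PSI`,
#'   `z`, `k`, `pairs` (0-based residue index pairs), `transform`,
#'   `flags`.
#' @examples
#' h <- generate_helix(100)
#' align_structures(h, rigid_copy(h, seed = 1))
#' @export
align_structures <- function(trace_q, trace_p, params = align_params()) {
  stopifnot(inherits(trace_q, "ca_trace"), inherits(trace_p, "ca_trace"))
  flags <- character(0)
  alignments <- list()

  if (min(trace_q$length, trace_p$length) < params$l_f) {
    flags <- c(flags, "residue_only")
    m <- min(trace_q$length, trace_p$length)
    if (m >= 3L) {
      idx <- seq_len(m) - 1L
      alignments <- list(cbind(q = idx, p = idx))
    }
  } else {
    frags_q <- decompose_fragments(trace_q, params$l_f)
    frags_p <- decompose_fragments(trace_p, params$l_f)
    smat <- fragment_score_matrix(frags_q, frags_p)
    seeds <- generate_seeds(frags_q, frags_p, params, score_matrix = smat)
    for (seed in seeds) {
      sub <- smat[seed$f_q + 1L, seed$f_p + 1L, drop = FALSE]
      path <- dp_align(sub, params$g_f)$pairs
      if (NROW(path) == 0L) next
      frag_path <- cbind(seed$f_q[path[, 1L] + 1L],
                         seed$f_p[path[, 2L] + 1L])
      r0 <- assemble_initial_alignment(frag_path, params$l_f)
      if (NROW(r0) >= 3L) alignments[[length(alignments) + 1L]] <- r0
    }
  }

  if (length(alignments) == 0L) {
    return(build_report(trace_q, trace_p,
                        matrix(integer(0), ncol = 2L), NULL, NA_real_,
                        params, flags))
  }

  best <- NULL
  for (round in seq_len(params$n_iter)) {
    results <- list()
    for (r in alignments) {
      refined <- tryCatch(
        residue_level_align(r, trace_q, trace_p, params),
        error = function(e) NULL)
      if (is.null(refined) || NROW(refined$pairs) < 3L) next
      ms <- max_subset(refined$pairs, trace_q, trace_p, params)
      if (ms$degenerate || NROW(ms$pairs_next) == 0L) next
      results[[length(results) + 1L]] <-
        list(tm = ms$tm, pairs = ms$pairs_next, transform = ms$transform)
    }
    if (length(results) == 0L) break

    for (res in results) {
      if (is.null(best) || res$tm > best$tm) best <- res
    }
    results <- filter_redundant_alignments(results, params$jaccard_threshold)
    new_alignments <- lapply(results, `[[`, "pairs")

    # early exit: the surviving alignment set is stable, so further
    # rounds cannot change the running best
    if (round > 1L && identical(lapply(alignments, as.integer),
                                lapply(new_alignments, as.integer))) break
    alignments <- new_alignments
  }

  if (is.null(best)) {
    return(build_report(trace_q, trace_p,
                        matrix(integer(0), ncol = 2L), NULL, NA_real_,
                        params, flags))
  }
  build_report(trace_q, trace_p, best$pairs, best$transform, best$tm,
               params, flags)
}

# Greedy Jaccard filter over candidate alignments (keep-best by TM-score);
# the same redundancy rule as the MFS filter, applied to residue-pair sets.
filter_redundant_alignments <- function(results, threshold) {
  if (length(results) <= 1L) return(results)
  ord <- order(-vapply(results, `[[`, numeric(1), "tm"))
  results <- results[ord]
  kept <- list()
  kept_keys <- list()
  for (res in results) {
    key <- paste(res$pairs[, 1L], res$pairs[, 2L])
    redundant <- any(vapply(kept_keys, function(k) {
      jaccard(key, k) >= threshold
    }, logical(1)))
    if (!redundant) {
      kept[[length(kept) + 1L]] <- res
      kept_keys[[length(kept_keys) + 1L]] <- key
    }
  }
  kept
}

#' Plan the comparison count of a database search
#'
#' @param n_targets Number of target structures.
#' @param db_sizes Integer vector of database partition sizes.
#' @return Total number of pairwise comparisons,
#'   `n_targets * sum(db_sizes)`.
#' @examples
#' plan_comparisons(100, c(6569, 1912))  # 848100
#' @export
plan_comparisons <- function(n_targets, db_sizes) {
  stopifnot(n_targets >= 1, all(db_sizes >= 0))
  as.numeric(n_targets) * sum(as.numeric(db_sizes))
}

#' One-against-all structure database search
#'
#' Aligns the target against every database structure and ranks the
#' reports by descending z-score.  Individual pair failures become
#' flagged rows; they never abort the batch.
#'
#' @param trace_q Target [ca_trace()].
#' @param db Non-empty list of database [ca_trace()]s.
#' @param params An [align_params()].
#' @param verbose Log the planned comparison count and progress to
#'   stderr.
#' @return An object of class `"structaln_search"`: a list of
#'   `"structaln"` reports sorted by descending z-score, with the summary
#'   table in `$table`.
#' @export
search_structures <- function(trace_q, db, params = align_params(),
                              verbose = TRUE) {
  stopifnot(inherits(trace_q, "ca_trace"), length(db) > 0L)
  if (verbose) {
    message(sprintf("planner: %d target x %d database structures = %.0f comparisons",
                    1L, length(db), plan_comparisons(1L, length(db))))
  }
  reports <- lapply(db, function(p) {
    tryCatch(align_structures(trace_q, p, params),
             error = function(e) {
               build_report(trace_q, p, matrix(integer(0), ncol = 2L),
                            NULL, NA_real_, params,
                            flags = paste0("error:", conditionMessage(e)))
             })
  })
  z <- vapply(reports, function(r) {
    if (is.na(r$z)) -Inf else r$z
  }, numeric(1))
  reports <- reports[order(-z)]
  out <- list(reports = reports,
              table = do.call(rbind, lapply(reports, report_row)),
              n_comparisons = plan_comparisons(1L, length(db)))
  class(out) <- "structaln_search"
  out
}

#' @export
print.structaln <- function(x, ...) {
  cat(sprintf("Structure alignment: %s (L=%d) vs %s (L=%d)\n",
              x$target_id, x$L_Q, x$db_id, x$L_P))
  if (x$Ne == 0L) {
    cat("  no alignment found; flags:", paste(x$flags, collapse = ","), "\n")
    return(invisible(x))
  }
  cat(sprintf("  Ne=%d  cRMSD=%.3f A  RMSD100=%.3f A  TM=%.4f  PSI=%.2f  z=%.2f\n",
              x$Ne, x$cRMSD, x$RMSD100, x$S_a, x$PSI, x$z))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}

#' @export
summary.structaln <- function(object, ...) {
  print(object)
  if (!is.null(object$transform)) print(object$transform)
  if (object$Ne > 0L) {
    cat(sprintf("  aligned span: target [%d..%d], database [%d..%d] (0-based)\n",
                min(object$pairs[, 1L]), max(object$pairs[, 1L]),
                min(object$pairs[, 2L]), max(object$pairs[, 2L])))
  }
  invisible(object)
}

#' @export
print.structaln_search <- function(x, ...) {
  cat(sprintf("One-against-all search: %.0f comparisons\n", x$n_comparisons))
  print(utils::head(x$table, 10L))
  if (nrow(x$table) > 10L) cat("...", nrow(x$table) - 10L, "more rows\n")
  invisible(x)
}

#' @export
as.data.frame.structaln_search <- function(x, ...) x$table
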