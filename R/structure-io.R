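#' C-alpha trace constructor
#'
#' An ordered backbone trace: one C-alpha coordinate per residue, N- to
#' C-terminus, with the author residue numbering kept for reporting while
#' all internal indexing is 0-based positional.
#'
#' @param id Structure identifier.
#' @param coords N x 3 numeric matrix of C-alpha coordinates, Angstrom.
#' @param residue_ids Integer author residue numbers (may be
#'   non-contiguous); defaults to `1:N`.
#' @param chain Single chain identifier character.
#' @return An object of class `"ca_trace"` with fields `id`, `chain`,
#'   `coords`, `residue_ids` and `length`.
#' @examples
#' ca_trace("toy", rbind(c(0, 0, 0), c(3.8, 0, 0)))
#' @export
ca_trace <- function(id, coords, residue_ids = NULL, chain = "A") {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  if (n < 1L) stop("empty trace")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != n) stop("residue_ids length must match coords")
  structure(list(id = as.character(id), chain = as.character(chain),
                 coords = coords, residue_ids = residue_ids,
                 length = n),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("C-alpha trace '%s' chain %s: %d residues (%d..%d)\n",
              x$id, x$chain, x$length,
              min(x$residue_ids), max(x$residue_ids)))
  invisible(x)
}

#' @export
length.ca_trace <- function(x) x$length

#' Read a C-alpha trace from a PDB file
#'
#' Reads the first model of a PDB file and extracts one C-alpha per
#' residue.  Alternate locations keep altloc `' '` or `'A'`; non-standard
#' residues carrying a C-alpha (e.g. MSE given as HETATM) are included;
#' calcium ions (HETATM with atom name CA but element Ca) are excluded.
#' Chain breaks (consecutive C-alpha distance > 4.5 Angstrom) are reported
#' as a warning but the trace is kept whole.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; if `NULL` the first chain containing
#'   C-alpha atoms is used.
#' @return A [ca_trace()].
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' write_ca_pdb(generate_helix(12), f)
#' read_ca_trace(f)
#' @export
read_ca_trace <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA" &
                atoms$alt %in% c("", " ", NA, "A") &
                !(atoms$type == "HETATM" & atoms$resid %in% c("CA", "ZN",
                                                             "MG", "NA")), ,
              drop = FALSE]
  if (nrow(ca) == 0L) stop("empty trace: no C-alpha atoms in ", path)
  if (is.null(chain)) {
    chain <- ca$chain[1L]
    if (is.na(chain)) chain <- " "
  } else if (!chain %in% ca$chain) {
    stop("chain not found: '", chain, "' in ", path)
  }
  sel <- if (is.na(ca$chain[1L]) && chain == " ") is.na(ca$chain)
         else !is.na(ca$chain) & ca$chain == chain
  ca <- ca[sel, , drop = FALSE]
  if (nrow(ca) == 0L) stop("empty trace: chain '", chain, "' has no C-alpha")
  # one CA per (resno, insert): keep the first in file order
  key <- paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
  ca <- ca[!duplicated(key), , drop = FALSE]
  coords <- cbind(ca$x, ca$y, ca$z)
  tr <- ca_trace(id = sub("\\.pdb$", "", basename(path)),
                 coords = coords, residue_ids = ca$resno, chain = chain)
  gaps <- which(sqrt(rowSums(diff(coords)^2)) > 4.5)
  if (length(gaps) > 0L) {
    warning(sprintf("%s: %d chain break(s) (C-alpha step > 4.5 A) at trace position(s) %s",
                    tr$id, length(gaps), paste(gaps, collapse = ",")))
  }
  tr
}

#' Write a C-alpha trace as a PDB file
#'
#' Emits one CA atom per residue (residue ALA, occupancy 1.00), enough for
#' round-tripping generated structures through [read_ca_trace()].
#'
#' @param trace A [ca_trace()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @examples
#' write_ca_pdb(generate_helix(5), tempfile(fileext = ".pdb"))
#' @export
write_ca_pdb <- function(trace, path) {
  stopifnot(inherits(trace, "ca_trace"))
  n <- trace$length
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(trace$coords)),
                   resno = trace$residue_ids,
                   resid = rep("ALA", n),
                   elety = rep("CA", n),
                   chain = rep(substr(trace$chain, 1L, 1L), n))
  invisible(path)
}

report_columns <- c("target_id", "db_id", "L_Q", "L_P", "Ne", "cRMSD",
                    "RMSD100", "TM_score", "PSI", "z_score", "flags")

#' Convert alignment reports to a data frame
#'
#' @param x A `"structaln"` object or list of them.
#' @param ... Unused.
#' @return A data frame with one row per comparison, columns `target_id`,
#'   `db_id`, `L_Q`, `L_P`, `Ne`, `cRMSD`, `RMSD100`, `TM_score`, `PSI`,
#'   `z_score`, `flags`.
#' @export
as.data.frame.structaln <- function(x, ...) {
  report_row(x)
}

report_row <- function(r) {
  num <- function(v) if (is.null(v) || length(v) == 0L) NA_real_ else v
  data.frame(target_id = r$target_id, db_id = r$db_id,
             L_Q = r$L_Q, L_P = r$L_P, Ne = r$Ne,
             cRMSD = num(r$cRMSD), RMSD100 = num(r$RMSD100),
             TM_score = num(r$S_a), PSI = num(r$PSI),
             z_score = num(r$z),
             flags = if (length(r$flags)) paste(r$flags, collapse = ",")
                     else "",
             stringsAsFactors = FALSE)
}

#' Write a TSV table of alignment reports
#'
#' One row per comparison, sorted by descending z-score (failed
#' comparisons, which carry no z-score, sort last).  Column order is
#' fixed: target_id, db_id, L_Q, L_P, Ne, cRMSD, RMSD100, TM_score, PSI,
#' z_score, flags.
#'
#' @param reports List of alignment reports (`"structaln"` objects); may
#'   be empty, which writes the header only.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_table <- function(reports, path) {
  if (inherits(reports, "structaln")) reports <- list(reports)
  if (length(reports) == 0L) {
    tab <- as.data.frame(stats::setNames(rep(list(character(0)),
                                             length(report_columns)),
                                         report_columns))
  } else {
    tab <- do.call(rbind, lapply(reports, report_row))
    ord <- order(-ifelse(is.na(tab$z_score), -Inf, tab$z_score))
    tab <- tab[ord, , drop = FALSE]
    for (col in c("cRMSD", "RMSD100")) tab[[col]] <- fmt_num(tab[[col]], 3L)
    tab$TM_score <- fmt_num(tab$TM_score, 4L)
    tab$PSI <- fmt_num(tab$PSI, 2L)
    tab$z_score <- fmt_num(tab$z_score, 2L)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

fmt_num <- function(v, digits) {
  ifelse(is.na(v), NA_character_, formatC(v, format = "f", digits = digits))
}

#' Write a residue-pair alignment file
#'
#' Plain-text block: header, the 3x3 rotation and translation of the final
#' superposition, then one line per aligned pair with target residue id,
#' database residue id and post-superposition distance (3 decimals,
#' Angstrom).
#'
#' @param report An alignment report from [align_structures()].
#' @param trace_q,trace_p The aligned [ca_trace()]s.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pair_alignment <- function(report, trace_q, trace_p, path) {
  stopifnot(inherits(report, "structaln"),
            inherits(trace_q, "ca_trace"), inherits(trace_p, "ca_trace"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# pair alignment: %s vs %s", report$target_id, report$db_id)
  wl("# Ne=%d cRMSD=%s TM=%s PSI=%s z=%s",
     report$Ne,
     fmt_or_na(report$cRMSD, 3L), fmt_or_na(report$S_a, 4L),
     fmt_or_na(report$PSI, 2L), fmt_or_na(report$z, 2L))
  tr <- if (!is.null(report$transform)) report$transform else identity_transform()
  for (k in 1:3) {
    wl("# R %s", paste(sprintf("%12.8f", tr$rotation[k, ]), collapse = " "))
  }
  wl("# t %s", paste(sprintf("%12.6f", tr$translation), collapse = " "))
  if (report$Ne > 0L) {
    qi <- report$pairs[, 1L] + 1L
    pj <- report$pairs[, 2L] + 1L
    d <- pair_distances(report$pairs, trace_q, trace_p, tr)
    for (k in seq_along(qi)) {
      wl("%d\t%d\t%.3f", trace_q$residue_ids[qi[k]],
         trace_p$residue_ids[pj[k]], d[k])
    }
  }
  invisible(path)
}

fmt_or_na <- function(v, digits) {
  if (is.null(v) || length(v) == 0L || is.na(v)) "NA"
  else formatC(v, format = "f", digits = digits)
}

# post-superposition distances of 0-based residue pairs
pair_distances <- function(pairs, trace_q, trace_p, transform) {
  if (NROW(pairs) == 0L) return(numeric(0))
  qt <- apply_transform(transform,
                        trace_q$coords[pairs[, 1L] + 1L, , drop = FALSE])
  pp <- trace_p$coords[pairs[, 2L] + 1L, , drop = FALSE]
  sqrt(rowSums((qt - pp)^2))
}
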