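#' Generate an ideal alpha-helical C-alpha trace
#'
#' Canonical alpha-helix geometry: 1.5 Angstrom rise and 100 degree twist
#' per residue on a 2.3 Angstrom radius, which gives the characteristic
#' ~3.8 Angstrom consecutive C-alpha spacing.
#'
#' @param n Residue count (>= 1).
#' @param rise Rise per residue along the helix axis, Angstrom.
#' @param twist Twist per residue, degrees.
#' @param radius Helix radius, Angstrom.
#' @param id Identifier for the trace.
#' @return A [ca_trace()].
#' @examples
#' h <- generate_helix(10)
#' sqrt(sum((h$coords[2, ] - h$coords[1, ])^2))  # ~3.8
#' @export
generate_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3,
                           id = "helix") {
  stopifnot(n >= 1)
  k <- seq_len(n) - 1
  theta <- k * twist * pi / 180
  ca_trace(id, cbind(radius * cos(theta), radius * sin(theta), k * rise))
}

# run code with a private, seeded RNG stream; the caller's RNG state is
# untouched
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Perturb a trace with isotropic Gaussian noise
#'
#' Adds independent `N(0, sigma^2)` noise to every coordinate component,
#' reproducibly from the seed; `sigma = 0` returns an identical copy.
#' The caller's RNG state is left untouched.
#'
#' @param trace A [ca_trace()].
#' @param sigma Per-coordinate noise standard deviation, Angstrom (>= 0).
#' @param seed Integer seed.
#' @return A new [ca_trace()].
#' @export
perturb_trace <- function(trace, sigma, seed = 1L) {
  stopifnot(inherits(trace, "ca_trace"), sigma >= 0)
  noise <- with_seed(seed, matrix(stats::rnorm(3L * trace$length, sd = sigma),
                                  ncol = 3L))
  ca_trace(paste0(trace$id, "_perturbed"), trace$coords + noise,
           trace$residue_ids, trace$chain)
}

#' Random-walk decoy chain
#'
#' Fixed-step self-avoiding random walk: every consecutive C-alpha
#' distance equals `step` and any placement closer than `min_sep` to a
#' non-neighbouring earlier residue is rejected and redrawn.  If the
#' per-step rejection budget is exhausted the whole chain restarts
#' deterministically from `seed + 1`.
#'
#' @param n Residue count (>= 1).
#' @param step Consecutive C-alpha distance, Angstrom.
#' @param min_sep Minimum distance to non-neighbouring residues,
#'   Angstrom.
#' @param seed Integer seed.
#' @param id Identifier for the trace.
#' @return A [ca_trace()].
#' @export
random_walk_trace <- function(n, step = 3.8, min_sep = 3.0, seed = 1L,
                              id = "decoy") {
  stopifnot(n >= 1)
  for (attempt in 0:50) {
    coords <- with_seed(seed + attempt, random_walk_attempt(n, step, min_sep))
    if (!is.null(coords)) {
      if (attempt > 0L) {
        message(sprintf("random_walk_trace: reseeded to %d after clash budget",
                        seed + attempt))
      }
      return(ca_trace(id, coords))
    }
  }
  stop("random walk failed to place a self-avoiding chain")
}

random_walk_attempt <- function(n, step, min_sep, budget = 100L) {
  coords <- matrix(0, n, 3L)
  for (i in seq_len(n)[-1L]) {
    placed <- FALSE
    for (try in seq_len(budget)) {
      dir <- stats::rnorm(3L)
      dir <- dir / sqrt(sum(dir^2))
      cand <- coords[i - 1L, ] + step * dir
      if (i > 2L) {
        d2 <- colSums((t(coords[seq_len(i - 2L), , drop = FALSE]) - cand)^2)
        if (min(d2) < min_sep^2) next
      }
      coords[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  coords
}

#' Rigidly transformed copy of a trace
#'
#' Applies a seeded random proper rotation (uniform unit quaternion) and
#' translation (components uniform on [-50, 50] Angstrom).  All internal
#' distances are preserved exactly.
#'
#' @param trace A [ca_trace()].
#' @param seed Integer seed.
#' @return A new [ca_trace()].
#' @export
rigid_copy <- function(trace, seed = 1L) {
  stopifnot(inherits(trace, "ca_trace"))
  tr <- with_seed(seed, {
    q <- stats::rnorm(4L)
    q <- q / sqrt(sum(q^2))
    rigid_transform(quaternion_rotation(q), stats::runif(3L, -50, 50))
  })
  ca_trace(paste0(trace$id, "_moved"), apply_transform(tr, trace$coords),
           trace$residue_ids, trace$chain)
}

quaternion_rotation <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
         3L, 3L, byrow = TRUE)
}

#' Build a synthetic structure from a fixture specification
#'
#' Convenience dispatcher over the generators, mirroring the CLI's
#' `simulate` subcommand.
#'
#' @param kind One of `"helix"`, `"perturbed_copy"`, `"random_walk"`,
#'   `"rigid_copy"`.
#' @param n Residue count.
#' @param sigma Noise level for `"perturbed_copy"`, Angstrom.
#' @param seed Integer seed.
#' @return A [ca_trace()].
#' @export
simulate_trace <- function(kind = c("helix", "perturbed_copy",
                                    "random_walk", "rigid_copy"),
                           n, sigma = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
         helix = generate_helix(n),
         perturbed_copy = perturb_trace(generate_helix(n), sigma, seed),
         random_walk = random_walk_trace(n, seed = seed),
         rigid_copy = rigid_copy(generate_helix(n), seed))
}
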