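# Synthetic structure sets with known ground truth.
#
# The planted-motif generator is the package's primary test substrate: it
# embeds rigid, noisy copies of one compact template motif into random-coil
# decoys, so recovery can be judged against recorded truth without any
# external structure data.

# uniformly random rotation matrix (random quaternion method)
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Self-avoiding random-coil structure
#'
#' A random walk with consecutive C-alpha spacing drawn uniformly in
#' [3.7, 3.9] Angstrom (the canonical ~3.8 A virtual bond) and a 2.5 A
#' self-avoidance radius between non-consecutive residues; residue symbols
#' are uniform over the 20-letter alphabet. Randomness comes from the
#' session RNG, so results are reproducible under \code{set.seed}.
#'
#' @param length Number of residues (>= 1).
#' @param id Structure label (default "coil").
#' @return A \code{\link{calpha_structure}}.
#' @export
random_coil_structure <- function(length, id = "coil") {
  if (length < 1) stop("length must be at least 1")
  n <- as.integer(length)
  repeat {
    xyz <- matrix(0, n, 3)
    ok <- TRUE
    for (i in seq_len(n - 1L) + 1L) {
      placed <- FALSE
      for (try in 1:200) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        p <- xyz[i - 1L, ] + stats::runif(1, 3.7, 3.9) * dir
        if (i > 2L) {
          dmin <- min(sqrt(rowSums((xyz[seq_len(i - 2L), , drop = FALSE] -
                                      matrix(p, i - 2L, 3, byrow = TRUE))^2)))
          if (dmin < 2.5) next
        }
        xyz[i, ] <- p
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break   # dead ends are rare; restart the whole walk when stuck
  }
  calpha_structure(id = id,
                   symbols = sample(amino_alphabet(), n, replace = TRUE),
                   xyz = xyz)
}

#' Ideal alpha-helix C-alpha template
#'
#' The compact motif template used by the planted-motif generator: rise
#' 1.5 A per residue, helix radius 2.3 A, 100 degrees of turn per residue.
#' Every adjacent residue pair sits well inside the 10 A clique radius.
#'
#' @param size Number of residues.
#' @return Numeric size x 3 coordinate matrix.
#' @export
helix_template <- function(size) {
  t <- seq_len(size) - 1
  ang <- t * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
}

#' Generate a planted-motif structure set
#'
#' Builds \code{n_structures} structures, each a self-avoiding random coil
#' of \code{decoy_length} residues into which a rigid copy of one
#' alpha-helical template motif is spliced at a random list position. Each
#' copy gets a uniformly random rotation, a translation placing it outside
#' the coil (no clashes), and isotropic Gaussian coordinate noise of scale
#' \code{noise_sigma} per coordinate. Motif residues carry identical symbols
#' across structures; the true motif indices are recorded per structure.
#'
#' @param n_structures Number of structures (>= 2).
#' @param motif_size Residues in the planted motif (>= 3).
#' @param decoy_length Residues in the decoy coil (>= motif_size).
#' @param noise_sigma Noise scale in Angstrom per coordinate.
#' @param rng_seed Optional seed applied via \code{set.seed} before drawing.
#' @return A list of class \code{"planted_motif_fixture"}: \code{structures}
#'   (list of \code{\link{calpha_structure}}), \code{truth} (list of integer
#'   index vectors, consecutive in each structure's residue list),
#'   \code{motif_symbols}, \code{motif_size}, \code{noise_sigma}.
#' @export
generate_planted_motif_set <- function(n_structures, motif_size, decoy_length,
                                       noise_sigma = 0.1, rng_seed = NULL) {
  if (motif_size < 3) stop("motif_size must be at least 3")
  if (decoy_length < motif_size) stop("decoy_length must be >= motif_size")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  template <- helix_template(motif_size)
  motif_symbols <- sample(amino_alphabet(), motif_size, replace = TRUE)
  structures <- vector("list", n_structures)
  truth <- vector("list", n_structures)
  for (i in seq_len(n_structures)) {
    coil <- random_coil_structure(decoy_length, id = sprintf("synth%02d", i))
    rot <- .random_rotation()
    placed <- template %*% t(rot)
    ctr <- colMeans(coil$xyz)
    reach <- max(sqrt(rowSums(sweep(coil$xyz, 2, ctr)^2)))
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    shift <- ctr + (reach + 12) * dir - colMeans(placed)
    placed <- sweep(placed, 2, shift, `+`) +
      matrix(stats::rnorm(3 * motif_size, sd = noise_sigma), motif_size, 3)
    u <- sample.int(decoy_length + 1L, 1L) - 1L   # splice after residue u
    xyz <- rbind(coil$xyz[seq_len(u), , drop = FALSE], placed,
                 coil$xyz[seq.int(u + 1L, length.out = decoy_length - u), ,
                          drop = FALSE])
    symbols <- c(coil$symbols[seq_len(u)], motif_symbols,
                 coil$symbols[seq.int(u + 1L, length.out = decoy_length - u)])
    structures[[i]] <- calpha_structure(id = coil$id, symbols = symbols,
                                        xyz = xyz)
    truth[[i]] <- seq.int(u + 1L, length.out = motif_size)
  }
  structure(list(structures = structures, truth = truth,
                 motif_symbols = motif_symbols,
                 motif_size = as.integer(motif_size),
                 noise_sigma = noise_sigma),
            class = "planted_motif_fixture")
}

#' Fingerprints present in a fixture's planted motif
#'
#' The sorted-symbol triplets of all residue triples of the planted motif
#' that satisfy the clique radius in the template geometry - the natural
#' fingerprint restriction when benchmarking recovery of a known motif.
#'
#' @param fixture A \code{\link{generate_planted_motif_set}} result.
#' @param radius Clique radius in Angstrom (default 10).
#' @return Character vector of sorted three-letter fingerprints.
#' @export
planted_motif_fingerprints <- function(fixture, radius = 10) {
  s <- fixture$structures[[1L]]
  idx <- fixture$truth[[1L]]
  tri <- .structure_triangles(
    calpha_structure("motif", s$symbols[idx], s$xyz[idx, , drop = FALSE]),
    radius)
  unique(tri$key)
}
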