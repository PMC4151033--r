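# The main entry point: fingerprint-driven motif search over N structures.

#' Multiple local structural motif discovery by Gibbs sampling
#'
#' Searches a set of protein structures for conserved local substructures of
#' \code{w} residues, one per structure, scored by average pairwise
#' superposition RMSD of their C-alpha coordinates. For every amino-acid
#' triplet fingerprint the sampler (i) bootstraps an alignment of
#' three-residue seeds by Gibbs sampling over distance-geometry similarity,
#' (ii) extends seed alignments whose average RMSD passes the seed gate to
#' width \code{w}, adding one Gibbs-sampled column at a time, and (iii)
#' refines the result by repeatedly deleting the worst column (maximum
#' badness) and re-extending. Collected alignments are ranked by ascending
#' average RMSD and greedily filtered for overlap.
#'
#' @param structures List of \code{\link{calpha_structure}} objects (N >= 2,
#'   each at least \code{w} residues), or a character vector of PDB file
#'   paths.
#' @param w Alignment width (>= 3). No universal default exists: it is
#'   family-specific, so it must be supplied.
#' @param alpha,iter_refine,avg_overlap,seed_rmsd_gate,candidate_radius,max_fingerprints,ordered_fingerprints,max_steps,rng_seed
#'   See \code{\link{motif_params}}.
#' @param fingerprints Optional character vector restricting the search to
#'   these triplet fingerprints (default: the full enumeration up to
#'   \code{max_fingerprints}).
#' @param table Substitution table for the extension phase (default
#'   \code{\link{blosum_similarity_table}()}).
#' @param verbose Emit per-fingerprint progress messages.
#' @return An object of class \code{"gibbsmotif"}: a list with
#'   \code{alignments} (ranked, overlap-filtered \code{"motif_alignment"}
#'   records), \code{n_found} (alignments collected before filtering),
#'   \code{n_fingerprints} (fingerprints searched), \code{params},
#'   \code{structure_ids}, and the matched \code{call}. Methods:
#'   \code{print}, \code{summary}, \code{plot}, \code{as.data.frame}.
#' @examples
#' set.seed(7)
#' fx <- generate_planted_motif_set(3, motif_size = 6, decoy_length = 30,
#'                                  noise_sigma = 0.05)
#' fit <- gibbsmotif(fx$structures, w = 6, rng_seed = 1,
#'                   fingerprints = planted_motif_fingerprints(fx))
#' fit
#' @export
gibbsmotif <- function(structures, w, alpha = 0.05, iter_refine = 10L,
                       avg_overlap = 50, seed_rmsd_gate = 1.0,
                       candidate_radius = 10.0, max_fingerprints = 8000L,
                       ordered_fingerprints = FALSE, max_steps = 5000L,
                       rng_seed = 1L, fingerprints = NULL,
                       table = blosum_similarity_table(), verbose = FALSE) {
  cl <- match.call()
  if (is.character(structures))
    structures <- lapply(structures, read_calpha_structure)
  if (length(structures) < 2L)
    stop("need at least two structures")
  if (!all(vapply(structures, inherits, logical(1), "calpha_structure")))
    stop("structures must be calpha_structure objects or PDB file paths")
  params <- motif_params(w = w, alpha = alpha, iter_refine = iter_refine,
                         avg_overlap = avg_overlap,
                         seed_rmsd_gate = seed_rmsd_gate,
                         candidate_radius = candidate_radius,
                         max_fingerprints = max_fingerprints,
                         ordered_fingerprints = ordered_fingerprints,
                         max_steps = max_steps, rng_seed = rng_seed)
  short <- vapply(structures, length, integer(1)) < params$w
  if (any(short))
    stop("structure(s) shorter than w: ",
         paste(vapply(structures[short], `[[`, character(1), "id"),
               collapse = ", "))
  set.seed(params$rng_seed)

  # one triangle scan per structure; fingerprints then resolve by key lookup
  tris <- lapply(structures, .structure_triangles, radius = params$candidate_radius)
  if (is.null(fingerprints))
    fingerprints <- enumerate_fingerprints(params$max_fingerprints)
  if (!params$ordered_fingerprints) {
    fingerprints <- unique(.sort_key(fingerprints))
    if (verbose)
      message(length(fingerprints), " distinct fingerprint multisets to search")
  }
  log_table <- log(table)
  found <- list()
  for (fp in fingerprints) {
    if (params$ordered_fingerprints) {
      cands <- lapply(structures, enumerate_seed_candidates, fingerprint = fp,
                      radius = params$candidate_radius, ordered = TRUE)
    } else {
      key <- .sort_key(fp)
      cands <- lapply(tris, function(tr) tr$idx[tr$key == key, , drop = FALSE])
    }
    if (any(vapply(cands, nrow, integer(1)) == 0L)) next
    seed_rows <- bootstrap_phase(structures, fp, params, candidates = cands)
    if (is.null(seed_rows)) next
    gate <- average_pairwise_rmsd(seed_rows, structures)
    if (verbose)
      message(sprintf("%s: %s candidates, seed RMSD %.3f (%s)", fp,
                      paste(vapply(cands, nrow, integer(1)), collapse = "/"),
                      gate,
                      if (gate <= params$seed_rmsd_gate) "pass" else "reject"))
    if (gate > params$seed_rmsd_gate) next
    rows <- extend_alignment(structures, seed_rows, params, table = table)
    if (is.null(rows)) next
    rows <- refine_alignment(structures, rows, params, table = table)
    found[[length(found) + 1L]] <- .alignment_record(rows, structures, fp)
  }
  kept <- filter_overlapping(sort_alignments(found), params$avg_overlap)
  structure(list(alignments = kept, n_found = length(found),
                 n_fingerprints = length(fingerprints), params = params,
                 structure_ids = vapply(structures, `[[`, character(1), "id"),
                 call = cl),
            class = "gibbsmotif")
}

#' @export
print.gibbsmotif <- function(x, ...) {
  cat("Gibbs-sampling local structural motif search\n")
  cat(sprintf("  %d structures, w = %d, alpha = %g, IterRefine = %d\n",
              length(x$structure_ids), x$params$w, x$params$alpha,
              x$params$iter_refine))
  cat(sprintf("  %d fingerprints searched, %d alignments found, %d kept after overlap filter (<= %g%%)\n",
              x$n_fingerprints, x$n_found, length(x$alignments),
              x$params$avg_overlap))
  if (length(x$alignments)) {
    cat(sprintf("  best alignment: avg RMSD %.3f A (fingerprint %s)\n",
                x$alignments[[1L]]$rmsd, x$alignments[[1L]]$fingerprint))
  }
  invisible(x)
}

#' @export
summary.gibbsmotif <- function(object, n = 5L, ...) {
  print(object)
  k <- min(n, length(object$alignments))
  if (k > 0L) {
    cat("\nTop alignments:\n")
    for (i in seq_len(k)) print(object$alignments[[i]])
  }
  invisible(.alignment_table(object$alignments))
}

#' @export
as.data.frame.gibbsmotif <- function(x, ...) .alignment_table(x$alignments)

#' Plot a motif search result
#'
#' Displays the contact map of one input structure with the residues of one
#' reported alignment highlighted - the standard 2D signature used to read a
#' local structural motif off a fold.
#'
#' @param x A \code{"gibbsmotif"} object.
#' @param structures The structure list the search was run on.
#' @param which Rank of the alignment to highlight (default 1).
#' @param structure Index of the structure whose map is drawn (default 1).
#' @param cutoff Contact cutoff in Angstrom (default 10).
#' @param ... Passed to \code{image}.
#' @export
plot.gibbsmotif <- function(x, structures, which = 1L, structure = 1L,
                            cutoff = 10, ...) {
  s <- structures[[structure]]
  cm <- contact_map(s, cutoff)
  n <- nrow(cm)
  graphics::image(seq_len(n), seq_len(n), cm, col = c("white", "grey40"),
                  xlab = "residue", ylab = "residue",
                  main = sprintf("%s contact map (cutoff %g A)", s$id, cutoff),
                  useRaster = TRUE, ...)
  if (length(x$alignments) >= which) {
    idx <- x$alignments[[which]]$rows[structure, ]
    graphics::abline(v = idx, h = idx, col = grDevices::adjustcolor("red", 0.35))
    graphics::points(idx, idx, pch = 19, col = "red", cex = 0.7)
  }
  invisible(x)
}
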