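# The stochastic core: fingerprint-driven Gibbs sampling in three phases.
#
# Bootstrap finds an N-seed alignment (3 residues per structure) for one
# amino-acid triplet fingerprint; extension grows it one column at a time to
# width w; refinement repeatedly deletes the worst column (max badness) and
# re-extends. Each phase runs a Markov chain that resamples one structure's
# element at a time from probabilities proportional to its similarity score,
# and stops when the state has not changed for a stall count derived from the
# chain-miss probability bound, or when a hard step cap is reached.

#' Sampler parameter set
#'
#' Collects and validates every tunable of the motif search.
#'
#' @param w Target alignment width (>= 3).
#' @param alpha Stopping probability in (0, 1): the stall count is the
#'   largest k with ((N-1)/N)^k > alpha (see
#'   \code{\link{gibbs_iterations_bound}}). Default 0.05.
#' @param iter_refine Number of refinement iterations (default 10).
#' @param avg_overlap Overlap-filter threshold percentage in [0, 100]
#'   (default 50; 100 disables filtering).
#' @param seed_rmsd_gate Maximum average pairwise RMSD (Angstrom) a seed
#'   alignment may have to enter extension (default 1.0).
#' @param candidate_radius Distance cutoff in Angstrom for seed cliques and
#'   extension candidates (default 10.0).
#' @param max_fingerprints Cap on the fingerprint enumeration, at most
#'   20^3 = 8000 (default 8000).
#' @param ordered_fingerprints If TRUE a seed matches a fingerprint as an
#'   ordered triple; default FALSE matches as a multiset (both sorted).
#' @param max_steps Hard cap on Gibbs steps per chain (default 5000),
#'   guarding against chains that never concentrate.
#' @param rng_seed Integer seed for the run's single random stream.
#' @return A list of class \code{"motif_params"}.
#' @export
motif_params <- function(w, alpha = 0.05, iter_refine = 10L, avg_overlap = 50,
                         seed_rmsd_gate = 1.0, candidate_radius = 10.0,
                         max_fingerprints = 8000L,
                         ordered_fingerprints = FALSE,
                         max_steps = 5000L, rng_seed = 1L) {
  if (!is.numeric(w) || w < 3) stop("w must be at least 3")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  if (iter_refine < 0) stop("iter_refine must be non-negative")
  if (avg_overlap < 0 || avg_overlap > 100)
    stop("avg_overlap must lie in [0, 100]")
  if (seed_rmsd_gate <= 0) stop("seed_rmsd_gate must be positive")
  if (candidate_radius <= 0) stop("candidate_radius must be positive")
  if (max_fingerprints < 1 || max_fingerprints > 8000)
    stop("max_fingerprints must lie in 1..8000")
  structure(list(w = as.integer(w), alpha = alpha,
                 iter_refine = as.integer(iter_refine),
                 avg_overlap = avg_overlap,
                 seed_rmsd_gate = seed_rmsd_gate,
                 candidate_radius = candidate_radius,
                 max_fingerprints = as.integer(max_fingerprints),
                 ordered_fingerprints = isTRUE(ordered_fingerprints),
                 max_steps = as.integer(max_steps),
                 rng_seed = as.integer(rng_seed)),
            class = "motif_params")
}

#' Enumerate amino-acid triplet fingerprints
#'
#' Deterministic lexicographic enumeration of ordered amino-acid triples
#' ("AAA", "AAC", ...), truncated at \code{cap}. The full enumeration has
#' 20^3 = 8000 distinct ordered triplets.
#'
#' @param cap Number of fingerprints to return, in 1..8000.
#' @return Character vector of three-letter strings.
#' @export
enumerate_fingerprints <- function(cap = 8000L) {
  if (!is.numeric(cap) || cap < 1 || cap > 8000)
    stop("cap must lie in 1..8000")
  aa <- amino_alphabet()
  g <- expand.grid(c3 = aa, c2 = aa, c1 = aa, stringsAsFactors = FALSE)
  fp <- paste0(g$c1, g$c2, g$c3)
  fp[seq_len(as.integer(cap))]
}

.sort_key <- function(fp) {
  vapply(strsplit(fp, ""), function(x) paste(sort(x), collapse = ""),
         character(1))
}

# All residue triples (ascending index) whose pairwise distances are below
# radius, with sorted-symbol keys and internal distance triples.
.structure_triangles <- function(s, radius) {
  n <- length(s$symbols)
  adj <- s$dist < radius
  idx <- vector("list", n)
  cnt <- 0L
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] & seq_len(n) > i)
    if (length(nb) < 2L) next
    sub <- adj[nb, nb, drop = FALSE]
    pr <- which(sub & upper.tri(sub), arr.ind = TRUE)
    if (nrow(pr) == 0L) next
    cnt <- cnt + 1L
    idx[[cnt]] <- cbind(i, nb[pr[, 1]], nb[pr[, 2]])
  }
  if (cnt == 0L)
    return(list(idx = matrix(integer(0), 0, 3), key = character(0),
                dists = matrix(numeric(0), 0, 3)))
  tri <- do.call(rbind, idx[seq_len(cnt)])
  dimnames(tri) <- NULL
  key <- apply(matrix(s$symbols[tri], ncol = 3), 1,
               function(x) paste(sort(x), collapse = ""))
  d <- cbind(s$dist[tri[, c(1, 2), drop = FALSE]],
             s$dist[tri[, c(1, 3), drop = FALSE]],
             s$dist[tri[, c(2, 3), drop = FALSE]])
  list(idx = tri, key = key, dists = d)
}

#' Enumerate feasible seed candidates for a fingerprint
#'
#' A feasible seed is a residue triple whose members are pairwise closer
#' than \code{radius} and whose symbols match the fingerprint. By default a
#' seed matches as a multiset (the fingerprint "AAC" matches any spatial
#' arrangement of two A and one C, stored in ascending index order); with
#' \code{ordered = TRUE} every index permutation whose symbol sequence equals
#' the fingerprint exactly is returned.
#'
#' @param s A \code{\link{calpha_structure}}.
#' @param fingerprint Three-letter string.
#' @param radius Clique radius in Angstrom (default 10).
#' @param ordered Matching convention (default unordered).
#' @return Integer m x 3 matrix of residue index triples (possibly 0 rows).
#' @export
enumerate_seed_candidates <- function(s, fingerprint, radius = 10,
                                      ordered = FALSE) {
  stopifnot(inherits(s, "calpha_structure"))
  letters3 <- strsplit(fingerprint, "")[[1]]
  if (length(letters3) != 3L || !all(letters3 %in% amino_alphabet()))
    stop("fingerprint must be three standard one-letter codes")
  tri <- .structure_triangles(s, radius)
  if (!ordered) {
    hit <- tri$key == paste(sort(letters3), collapse = "")
    return(tri$idx[hit, , drop = FALSE])
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (r in which(tri$key == paste(sort(letters3), collapse = ""))) {
    t3 <- tri$idx[r, ]
    for (p in perms) {
      if (identical(s$symbols[t3[p]], letters3)) out[[length(out) + 1L]] <- t3[p]
    }
  }
  if (length(out) == 0L) return(matrix(integer(0), 0, 3))
  unique(do.call(rbind, out))
}

#' Stall count of the Gibbs chain
#'
#' The chain stops once the alignment has not changed for k consecutive
#' steps, where k is the largest integer with ((N-1)/N)^k > alpha - i.e. the
#' longest run for which the probability that some structure was never
#' selected still exceeds alpha.
#'
#' @param n_structures Number of structures N (>= 2).
#' @param alpha Probability threshold in (0, 1).
#' @return Non-negative integer.
#' @export
gibbs_iterations_bound <- function(n_structures, alpha) {
  if (!is.numeric(n_structures) || n_structures < 2)
    stop("need at least two structures")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  r <- (n_structures - 1) / n_structures
  k <- floor(log(alpha) / log(r))
  while (k > 0 && r^k <= alpha) k <- k - 1
  while (r^(k + 1) > alpha) k <- k + 1
  as.integer(max(0, k))
}

# distance triple (d12, d13, d23) per candidate row
.candidate_dists <- function(s, cand) {
  cbind(s$dist[cand[, c(1, 2), drop = FALSE]],
        s$dist[cand[, c(1, 3), drop = FALSE]],
        s$dist[cand[, c(2, 3), drop = FALSE]])
}

#' Bootstrap phase: Gibbs sampling of an N-seed alignment
#'
#' For one fingerprint, runs the Markov chain whose states are alignments of
#' N seeds (one feasible candidate per structure). Each step picks a
#' structure uniformly at random and resamples its seed from probabilities
#' proportional to \code{\link{seed_similarity}} over all of that
#' structure's feasible candidates. The chain starts from one uniformly drawn
#' candidate per structure and stops after
#' \code{\link{gibbs_iterations_bound}} consecutive unchanged steps (or at
#' the hard step cap).
#'
#' @param structures List of \code{\link{calpha_structure}} objects.
#' @param fingerprint Three-letter fingerprint string.
#' @param params A \code{\link{motif_params}} object.
#' @param candidates Optional precomputed list of candidate matrices (as
#'   returned by \code{\link{enumerate_seed_candidates}}), one per structure.
#' @return NULL if any structure has no feasible candidate; otherwise an
#'   integer N x 3 matrix of residue indices with attributes \code{steps}
#'   (chain length) and \code{stall} (final unchanged-run length).
#' @export
bootstrap_phase <- function(structures, fingerprint, params,
                            candidates = NULL) {
  n <- length(structures)
  if (is.null(candidates))
    candidates <- lapply(structures, enumerate_seed_candidates,
                         fingerprint = fingerprint,
                         radius = params$candidate_radius,
                         ordered = params$ordered_fingerprints)
  if (any(vapply(candidates, nrow, integer(1)) == 0L)) return(NULL)
  dtri <- lapply(seq_len(n), function(i)
    .candidate_dists(structures[[i]], candidates[[i]]))
  state <- vapply(candidates, function(m) sample.int(nrow(m), 1L), integer(1))
  k_stall <- gibbs_iterations_bound(n, params$alpha)
  lf <- log(.FACTOR_FLOOR); lp <- log(.PRODUCT_FLOOR)
  stall <- 0L; steps <- 0L
  while (stall < k_stall && steps < params$max_steps) {
    j <- sample.int(n, 1L)
    dj <- dtri[[j]]
    logsim <- numeric(nrow(dj))
    for (i in seq_len(n)) {
      if (i == j) next
      di <- dtri[[i]][state[i], ]
      ad <- abs(dj - matrix(di, nrow(dj), 3L, byrow = TRUE))
      logsim <- logsim - pmax(rowSums(log(pmax(ad, .FACTOR_FLOOR))), lp)
    }
    pr <- exp(logsim - max(logsim))
    new <- sample.int(length(pr), 1L, prob = pr)
    if (new == state[j]) stall <- stall + 1L else { state[j] <- new; stall <- 0L }
    steps <- steps + 1L
  }
  rows <- t(vapply(seq_len(n), function(i) candidates[[i]][state[i], ],
                   integer(3)))
  rownames(rows) <- vapply(structures, `[[`, character(1), "id")
  attr(rows, "steps") <- steps
  attr(rows, "stall") <- stall
  rows
}

# One Gibbs-sampled column: returns the rows matrix with one appended column,
# or NULL when some structure has no candidate residue within the radius.
.gibbs_column <- function(structures, rows, params, log_table) {
  n <- nrow(rows)
  cand <- vector("list", n)
  prof <- vector("list", n)
  syms <- vector("list", n)
  for (s in seq_len(n)) {
    d <- structures[[s]]$dist
    row_s <- rows[s, ]
    near <- which(.row_mins(d[, row_s, drop = FALSE]) <
                    params$candidate_radius)
    near <- setdiff(near, row_s)
    if (length(near) == 0L) return(NULL)
    cand[[s]] <- near
    prof[[s]] <- d[near, row_s, drop = FALSE]
    syms[[s]] <- structures[[s]]$symbols[near]
  }
  state <- vapply(cand, function(x) sample.int(length(x), 1L), integer(1))
  k_stall <- gibbs_iterations_bound(n, params$alpha)
  lp <- log(.PRODUCT_FLOOR)
  stall <- 0L; steps <- 0L
  while (stall < k_stall && steps < params$max_steps) {
    j <- sample.int(n, 1L)
    pj <- prof[[j]]
    m <- nrow(pj)
    logsc <- numeric(m)
    for (k in seq_len(n)) {
      if (k == j) next
      pk <- prof[[k]][state[k], ]
      ad <- abs(pj - matrix(pk, m, length(pk), byrow = TRUE))
      logsc <- logsc - pmax(rowSums(log(pmax(ad, .FACTOR_FLOOR))), lp)
      logsc <- logsc + log_table[syms[[j]], syms[[k]][state[k]]]
    }
    pr <- exp(logsc - max(logsc))
    new <- sample.int(m, 1L, prob = pr)
    if (new == state[j]) stall <- stall + 1L else { state[j] <- new; stall <- 0L }
    steps <- steps + 1L
  }
  newcol <- vapply(seq_len(n), function(s) cand[[s]][state[s]], integer(1))
  cbind(rows, newcol, deparse.level = 0)
}

# row-wise minimum of a numeric matrix
.row_mins <- function(m) do.call(pmin, as.data.frame(m))

#' Extension phase: grow an alignment to width w
#'
#' Starting from a seed alignment of width >= 3 whose average pairwise RMSD
#' passes the seed gate, adds one column per step until width w. Candidates
#' for a structure are its residues within the candidate radius of any
#' residue of that structure's current row (residues already in the row are
#' excluded); each column is sampled by one Gibbs sweep scored by
#' \code{\link{extension_score}}, with the same stall rule as the bootstrap.
#'
#' @param structures List of \code{\link{calpha_structure}} objects.
#' @param rows Integer N x w' matrix, w' >= 3.
#' @param params A \code{\link{motif_params}} object.
#' @param table Substitution table (default
#'   \code{\link{blosum_similarity_table}()}).
#' @return Integer N x w matrix, or NULL if any structure runs out of
#'   candidates at some step.
#' @export
extend_alignment <- function(structures, rows, params,
                             table = blosum_similarity_table()) {
  rows <- as.matrix(rows)
  if (ncol(rows) < 3L) stop("alignment width must be at least 3")
  if (ncol(rows) > params$w) stop("alignment already wider than w")
  gate <- average_pairwise_rmsd(rows, structures)
  if (gate > params$seed_rmsd_gate)
    stop(sprintf("seed gate violated: average RMSD %.3f > %.3f Angstrom",
                 gate, params$seed_rmsd_gate))
  log_table <- log(table)
  while (ncol(rows) < params$w) {
    nxt <- .gibbs_column(structures, rows, params, log_table)
    if (is.null(nxt)) return(NULL)
    rows <- nxt
  }
  rows
}

#' Refinement phase: replace the worst columns
#'
#' Repeats \code{iter_refine} times: compute \code{\link{badness}} for every
#' column, delete the column with the largest value (ties break to the lowest
#' index), and run one Gibbs extension step to restore width w. If the
#' extension step finds no candidates, the deleted column is restored and
#' refinement stops early.
#'
#' @inheritParams extend_alignment
#' @param rows Integer N x w matrix.
#' @return Integer N x w matrix.
#' @export
refine_alignment <- function(structures, rows, params,
                             table = blosum_similarity_table()) {
  rows <- as.matrix(rows)
  if (ncol(rows) != params$w) stop("refinement expects an alignment of width w")
  if (params$iter_refine == 0L) return(rows)
  log_table <- log(table)
  for (t in seq_len(params$iter_refine)) {
    b <- vapply(seq_len(ncol(rows)), function(k) badness(rows, structures, k),
                numeric(1))
    kk <- which.max(b)   # ties resolve to the lowest column index
    reduced <- rows[, -kk, drop = FALSE]
    nxt <- .gibbs_column(structures, reduced, params, log_table)
    if (is.null(nxt)) return(rows)
    rows <- nxt
  }
  rows
}
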