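# Closed-form similarity scores driving the Gibbs transitions.
#
# All scores are functions of intra-structure C-alpha distances only, so they
# are invariant under rigid transforms of any input structure. The raw
# distance-discrepancy products (pair_dist_seeds, pair_dist_aligned, badness)
# are returned unfloored - they are exactly zero for identical geometry. The
# similarity scores that invert such products (seed_similarity, sim_dist)
# floor every |Dist - Dist| factor and every product at a small epsilon
# before inversion, so that geometrically perfect candidates are maximally,
# finitely likely instead of dividing by zero. Inside the sampler the same
# quantities are accumulated in log space to avoid under/overflow when many
# factors multiply.

.FACTOR_FLOOR <- 1e-6
.PRODUCT_FLOOR <- 1e-6

# seeds are lists: list(structure = index into the structures list,
#                       idx = integer triple of residue indices)
.seed_dist_triple <- function(seed, structures) {
  s <- structures[[seed$structure]]
  i <- seed$idx
  if (length(i) != 3L || anyDuplicated(i))
    stop("malformed seed: need three distinct residue indices")
  c(s$dist[i[1], i[2]], s$dist[i[1], i[3]], s$dist[i[2], i[3]])
}

#' Pairwise distance score between two seeds
#'
#' Product over the three internal residue pairs (i < j) of the absolute
#' difference between the corresponding intra-structure C-alpha distances of
#' the two seeds. Zero exactly when the two triples have identical internal
#' geometry.
#'
#' @param a,b Seeds: lists with elements \code{structure} (index into
#'   \code{structures}) and \code{idx} (integer triple of residue indices).
#' @param structures List of \code{\link{calpha_structure}} objects.
#' @return Non-negative number; symmetric in \code{a} and \code{b}.
#' @export
pair_dist_seeds <- function(a, b, structures) {
  da <- .seed_dist_triple(a, structures)
  db <- .seed_dist_triple(b, structures)
  prod(abs(da - db))
}

#' Similarity of a candidate seed against a seed alignment
#'
#' The inverse of the product over all current seeds (except the one being
#' replaced) of their \code{\link{pair_dist_seeds}} against the candidate,
#' each product floored at \code{floor} before inversion. Strictly positive
#' and finite for every feasible input.
#'
#' @param x Candidate seed belonging to structure \code{j}.
#' @param current List of N seeds, one per structure.
#' @param j Index of the row being replaced.
#' @param structures List of \code{\link{calpha_structure}} objects.
#' @param floor Lower bound applied to each pairwise product (default 1e-6).
#' @return Positive finite similarity score.
#' @export
seed_similarity <- function(x, current, j, structures, floor = .PRODUCT_FLOOR) {
  n <- length(current)
  if (j < 1L || j > n) stop("replaced row j out of range")
  pd <- vapply(current[-j], function(s) pair_dist_seeds(x, s, structures),
               numeric(1))
  1 / prod(pmax(pd, floor))
}

#' Symbol similarity of a candidate residue
#'
#' Product over the other rows of the substitution-table similarity between
#' the candidate's amino-acid symbol and each currently sampled candidate's
#' symbol.
#'
#' @param x_symbol One-letter code of the candidate residue.
#' @param candidate_symbols Character vector of N one-letter codes (current
#'   candidate alignment, one per structure).
#' @param j Index of the row being replaced.
#' @param table Substitution table from
#'   \code{\link{blosum_similarity_table}} (strictly positive entries).
#' @return Positive similarity score.
#' @export
sim_symb <- function(x_symbol, candidate_symbols, j, table) {
  aa <- amino_alphabet()
  if (!(x_symbol %in% aa) || !all(candidate_symbols %in% aa))
    stop("unknown residue symbol")
  if (j < 1L || j > length(candidate_symbols)) stop("replaced row j out of range")
  prod(table[x_symbol, candidate_symbols[-j]])
}

# log PairDist of two distance profiles with factor and product floors
.log_pairdist_profile <- function(dx, dk,
                                  factor_floor = .FACTOR_FLOOR,
                                  product_floor = .PRODUCT_FLOOR) {
  max(sum(log(pmax(abs(dx - dk), factor_floor))), log(product_floor))
}

#' Distance-profile similarity of a candidate residue (extension phase)
#'
#' For each other structure k, the candidate's distance profile to its own
#' row (distances from residue \code{x} to each already-aligned residue of
#' row \code{j}, column by column) is compared with the profile of that
#' structure's currently sampled candidate; the absolute differences are
#' multiplied across columns into a pairwise product, and the similarity is
#' the inverse of the product of these pairwise products, with factor and
#' product floors applied before inversion.
#'
#' @param x Residue index (in structure \code{j}) of the candidate.
#' @param candidates Integer vector of N residue indices: the current
#'   candidate alignment, one per structure.
#' @param j Index of the row being replaced.
#' @param rows Integer N x w' matrix: the current substructure alignment.
#' @param structures List of \code{\link{calpha_structure}} objects.
#' @param floor Product floor (default 1e-6).
#' @return Positive finite similarity score.
#' @export
sim_dist <- function(x, candidates, j, rows, structures, floor = .PRODUCT_FLOOR) {
  rows <- as.matrix(rows)
  n <- nrow(rows)
  if (length(candidates) != n)
    stop("candidates must supply one residue per structure")
  if (j < 1L || j > n) stop("replaced row j out of range")
  dx <- structures[[j]]$dist[x, rows[j, ]]
  logs <- 0
  for (k in seq_len(n)) {
    if (k == j) next
    dk <- structures[[k]]$dist[candidates[k], rows[k, ]]
    if (length(dk) != length(dx)) stop("width mismatch between rows")
    logs <- logs + .log_pairdist_profile(dx, dk, product_floor = floor)
  }
  exp(-logs)
}

#' Combined extension score of a candidate residue
#'
#' The product of \code{\link{sim_symb}} and \code{\link{sim_dist}}: the
#' Gibbs transition weight used when growing an alignment by one column.
#'
#' @inheritParams sim_dist
#' @param table Substitution table (see \code{\link{blosum_similarity_table}}).
#' @return Positive score.
#' @export
extension_score <- function(x, candidates, j, rows, structures, table) {
  xs <- structures[[j]]$symbols[x]
  cs <- vapply(seq_along(candidates),
               function(k) structures[[k]]$symbols[candidates[k]], character(1))
  sim_symb(xs, cs, j, table) * sim_dist(x, candidates, j, rows, structures)
}

#' Aligned-pair distance score of one column entry pair
#'
#' For rows i and j of an alignment and column k, the product over all other
#' columns h of the absolute difference between Dist(R[i,k], R[i,h]) and
#' Dist(R[j,k], R[j,h]), each distance taken within its own structure. Zero
#' when the two rows place column k identically relative to the rest.
#'
#' @param rows Integer N x w alignment matrix (w >= 2).
#' @param structures List of \code{\link{calpha_structure}} objects.
#' @param i,j Row indices.
#' @param k Column index.
#' @return Non-negative number; symmetric in i and j.
#' @export
pair_dist_aligned <- function(rows, structures, i, j, k) {
  rows <- as.matrix(rows)
  n <- nrow(rows); w <- ncol(rows)
  if (w < 2L) stop("alignment width must be at least 2")
  if (any(c(i, j) < 1L) || any(c(i, j) > n) || k < 1L || k > w)
    stop("row or column index out of range")
  h <- setdiff(seq_len(w), k)
  di <- structures[[i]]$dist[rows[i, k], rows[i, h]]
  dj <- structures[[j]]$dist[rows[j, k], rows[j, h]]
  prod(abs(di - dj))
}

#' Badness of an alignment column
#'
#' Sum over all row pairs i < j of \code{\link{pair_dist_aligned}} for the
#' given column: the refinement phase deletes the column maximising this.
#'
#' @inheritParams pair_dist_aligned
#' @return Non-negative number.
#' @export
badness <- function(rows, structures, k) {
  rows <- as.matrix(rows)
  n <- nrow(rows)
  tot <- 0
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      tot <- tot + pair_dist_aligned(rows, structures, i, j, k)
  tot
}

#' Normalise similarity scores into transition probabilities
#'
#' @param scores Non-empty vector of positive finite similarity scores.
#' @return Probability vector proportional to \code{scores}, summing to 1.
#' @export
transition_probabilities <- function(scores) {
  if (length(scores) == 0L) stop("no candidate scores")
  if (!all(is.finite(scores)) || any(scores <= 0))
    stop("scores must be positive and finite")
  scores / sum(scores)
}

#' Strictly positive substitution table from a log-odds matrix
#'
#' Builds the 20 x 20 similarity table used by \code{\link{sim_symb}}. The
#' default source is BLOSUM62; because raw BLOSUM log-odds entries are
#' negative for many pairs (which would break a product of similarities), the
#' default transform maps each score s to 2^s, preserving order while making
#' every entry strictly positive. \code{"shift"} instead adds
#' \code{1 - min(s)}, and \code{"raw"} keeps the matrix as is (only valid for
#' matrices that are already strictly positive).
#'
#' @param name Matrix name available in \code{Biostrings} data
#'   (e.g. "BLOSUM62", "BLOSUM50", "PAM30"), or a matrix supplied via
#'   \code{matrix}.
#' @param transform One of \code{"pow2"}, \code{"shift"}, \code{"raw"}.
#' @param matrix Optional 20 x 20 (or larger) numeric matrix with amino-acid
#'   dimnames, overriding \code{name}.
#' @return Numeric 20 x 20 matrix with dimnames over
#'   \code{\link{amino_alphabet}}.
#' @export
blosum_similarity_table <- function(name = "BLOSUM62",
                                    transform = c("pow2", "shift", "raw"),
                                    matrix = NULL) {
  transform <- match.arg(transform)
  if (is.null(matrix)) {
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    matrix <- get(name, envir = env)
  }
  aa <- amino_alphabet()
  if (!all(aa %in% rownames(matrix)) || !all(aa %in% colnames(matrix)))
    stop("substitution matrix must cover the 20 standard amino acids")
  m <- matrix[aa, aa]
  m <- switch(transform,
              pow2 = 2^m,
              shift = m + (1 - min(m)),
              raw = m)
  if (any(m <= 0))
    stop("substitution table entries must be strictly positive; choose a transform")
  if (max(abs(m - t(m))) > 1e-9)
    stop("substitution matrix must be symmetric")
  if (any(diag(m) < apply(m, 1, max)))
    warning("some identical pairs score below a mismatch in the same row")
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-delimited matrix format used by NCBI BLAST data
#' files ('#' comment lines, a header row of residue letters, one labelled
#' row per residue).
#'
#' @param path File path.
#' @return Numeric matrix with the file's row/column letters as dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- utils::read.table(text = lines[-1], row.names = 1,
                            col.names = c("aa", header))
  m <- as.matrix(body)
  storage.mode(m) <- "double"
  colnames(m) <- header
  m
}
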