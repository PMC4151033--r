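# C-alpha structure model and PDB I/O.

#' Standard amino-acid one-letter alphabet
#'
#' The 20 standard one-letter amino-acid codes in lexicographic order. This is
#' the alphabet of triplet fingerprints (20^3 = 8000 ordered triplets) and of
#' substitution-table lookups.
#'
#' @return Character vector of length 20.
#' @export
amino_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Construct a C-alpha structure
#'
#' Builds the single-point-per-residue representation used throughout the
#' package: one C-alpha coordinate per residue plus the cached all-pairs
#' distance matrix. All scoring in the sampler is a function of this distance
#' matrix only, so a structure is fully described by its coordinates, residue
#' symbols and (for reporting) the original residue numbers.
#'
#' @param id Character label for the structure.
#' @param symbols Character vector of one-letter amino-acid codes.
#' @param xyz Numeric matrix, one row per residue, three columns (Angstrom).
#' @param resno Integer vector of original residue numbers (defaults to
#'   \code{seq_along(symbols)}).
#' @param chain Single chain identifier character (default \code{"A"}).
#' @return An object of class \code{"calpha_structure"}: a list with elements
#'   \code{id}, \code{symbols}, \code{resno}, \code{chain}, \code{xyz} and the
#'   precomputed distance matrix \code{dist}.
#' @export
calpha_structure <- function(id, symbols, xyz, resno = seq_along(symbols),
                             chain = "A") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L)
    stop("xyz must have three columns")
  n <- length(symbols)
  if (nrow(xyz) != n)
    stop("symbols and xyz disagree on the number of residues")
  if (n < 1L)
    stop("empty structure: no residues")
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates")
  bad <- !(symbols %in% amino_alphabet())
  if (any(bad))
    stop("unknown residue symbol(s): ", paste(unique(symbols[bad]), collapse = ", "))
  if (length(resno) != n)
    stop("resno length mismatch")
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- NULL
  structure(list(id = as.character(id), symbols = as.character(symbols),
                 resno = as.integer(resno), chain = as.character(chain)[1L],
                 xyz = xyz, dist = d),
            class = "calpha_structure")
}

#' @export
print.calpha_structure <- function(x, ...) {
  cat(sprintf("C-alpha structure '%s': %d residues, chain %s\n",
              x$id, length(x$symbols), x$chain))
  seqstr <- paste(x$symbols, collapse = "")
  if (nchar(seqstr) > 60) seqstr <- paste0(substr(seqstr, 1, 57), "...")
  cat(" ", seqstr, "\n")
  invisible(x)
}

#' @export
length.calpha_structure <- function(x) length(x$symbols)

# Map a three-letter residue name to a one-letter code, or NA if nonstandard.
# MSE (selenomethionine) is folded into M so the 20-letter fingerprint
# alphabet stays valid; other nonstandard residues are dropped by the reader.
.aa3to1 <- function(resid) {
  resid[resid == "MSE"] <- "MET"
  one <- bio3d::aa321(resid)
  one[!(one %in% amino_alphabet())] <- NA_character_
  one
}

#' Read a protein structure as C-alpha coordinates
#'
#' Parses a PDB-format file (or raw PDB text) and keeps one C-alpha atom per
#' residue of a single chain. Altloc duplicates resolve to the first-listed
#' conformer; residues without a C-alpha atom, and nonstandard residues other
#' than MSE (mapped to M), are skipped with a warning. Only the first model of
#' a multi-model file is read.
#'
#' @param pdb Path to a PDB file, or a character string containing PDB text
#'   (recognised by embedded newlines).
#' @param chain Optional chain identifier; default is the first chain that
#'   carries a C-alpha atom.
#' @param id Structure label; defaults to the file base name.
#' @return A \code{\link{calpha_structure}}.
#' @export
read_calpha_structure <- function(pdb, chain = NULL, id = NULL) {
  if (length(pdb) != 1L || !is.character(pdb))
    stop("pdb must be a single file path or PDB text string")
  if (grepl("\n", pdb, fixed = TRUE) || !file.exists(pdb)) {
    if (!grepl("\n", pdb, fixed = TRUE))
      stop("file not found: ", pdb)
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    writeLines(pdb, tf)
    path <- tf
    if (is.null(id)) id <- "structure"
  } else {
    path <- pdb
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(pdb))
  }
  p <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                error = function(e) stop("PDB parse error: ", conditionMessage(e)))
  at <- p$atom
  # CA atoms; MSE arrives as HETATM but is a backbone residue here
  bb <- at[at$type == "ATOM" | at$resid == "MSE", , drop = FALSE]
  ca <- bb[bb$elety == "CA", , drop = FALSE]
  no_ca <- setdiff(paste(bb$chain, bb$resno, bb$insert),
                   paste(ca$chain, ca$resno, ca$insert))
  if (length(no_ca))
    warning("skipping ", length(no_ca), " residue(s) without a C-alpha atom")
  if (nrow(ca) == 0L)
    stop("empty structure: no C-alpha atoms in input")
  if (is.null(chain)) {
    chain <- ca$chain[1L]
    if (is.na(chain)) chain <- ""
  }
  sel_chain <- if (identical(chain, "")) is.na(ca$chain) else
    !is.na(ca$chain) & ca$chain == chain
  ca <- ca[sel_chain, , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("empty structure: no C-alpha atoms on chain '", chain, "'")
  # first-listed altloc wins, per residue (number + insertion code)
  rkey <- paste(ca$resno, ca$insert)
  keep <- !duplicated(rkey)
  ca <- ca[keep, , drop = FALSE]
  bad <- !is.finite(ca$x) | !is.finite(ca$y) | !is.finite(ca$z)
  if (any(bad))
    stop("malformed coordinate fields at atom serial(s): ",
         paste(ca$eleno[bad], collapse = ", "))
  one <- .aa3to1(ca$resid)
  if (anyNA(one)) {
    warning("dropping ", sum(is.na(one)), " nonstandard residue(s): ",
            paste(unique(ca$resid[is.na(one)]), collapse = ", "))
    ca <- ca[!is.na(one), , drop = FALSE]
    one <- one[!is.na(one)]
  }
  if (nrow(ca) == 0L)
    stop("empty structure: no standard residues with C-alpha atoms")
  calpha_structure(id = id, symbols = one,
                   xyz = cbind(ca$x, ca$y, ca$z),
                   resno = ca$resno,
                   chain = if (identical(chain, "")) " " else chain)
}

#' Write a C-alpha structure as PDB
#'
#' Emits one ATOM record per residue (CA atoms only), suitable for round-trip
#' reading with \code{\link{read_calpha_structure}} at PDB fixed-column
#' precision (1e-3 Angstrom).
#'
#' @param s A \code{\link{calpha_structure}}.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_calpha_pdb <- function(s, file) {
  stopifnot(inherits(s, "calpha_structure"))
  aa123 <- bio3d::aa123(s$symbols)
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(s$xyz)),
                   resno = s$resno,
                   resid = aa123,
                   chain = rep(s$chain, length(s$symbols)),
                   elety = rep("CA", length(s$symbols)))
  invisible(file)
}

#' One-letter sequence of a structure, optionally as FASTA
#'
#' @param s A \code{\link{calpha_structure}}.
#' @param file Optional path; when given, the sequence is written in FASTA
#'   format with the structure id as header.
#' @return The sequence as a single string (invisibly when writing).
#' @export
structure_sequence <- function(s, file = NULL) {
  stopifnot(inherits(s, "calpha_structure"))
  seqstr <- paste(s$symbols, collapse = "")
  if (!is.null(file)) {
    writeLines(c(paste0(">", s$id), seqstr), file)
    return(invisible(seqstr))
  }
  seqstr
}

#' Euclidean distance between two residues
#'
#' @param s A \code{\link{calpha_structure}}.
#' @param i,j Residue indices (1-based).
#' @return Distance in Angstrom.
#' @export
residue_distance <- function(s, i, j) {
  stopifnot(inherits(s, "calpha_structure"))
  n <- length(s$symbols)
  if (any(c(i, j) < 1L) || any(c(i, j) > n))
    stop("residue index out of range")
  s$dist[i, j]
}

#' Binary contact map of a structure
#'
#' Residues i != j are in contact when their C-alpha distance is strictly
#' below the cutoff; typical cutoffs are 7-12 Angstrom. The diagonal is zero.
#'
#' @param s A \code{\link{calpha_structure}}.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @return Symmetric 0/1 integer matrix.
#' @export
contact_map <- function(s, cutoff) {
  stopifnot(inherits(s, "calpha_structure"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive number")
  m <- (s$dist < cutoff) * 1L
  diag(m) <- 0L
  m
}
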