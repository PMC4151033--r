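# Ranking, overlap filtering and evaluation of reported alignments.
#
# An alignment record is a list with elements rows (integer N x w matrix of
# internal residue indices, rownames = structure ids), resno (same shape,
# original residue numbers), rmsd (average pairwise superposition RMSD),
# fingerprint, and - once filtered - perc (overlap percentage against the
# alignments kept before it).

.alignment_record <- function(rows, structures, fingerprint = NA_character_) {
  ids <- vapply(structures, `[[`, character(1), "id")
  rownames(rows) <- ids
  resno <- rows
  for (i in seq_len(nrow(rows)))
    resno[i, ] <- structures[[i]]$resno[rows[i, ]]
  structure(list(rows = rows, resno = resno,
                 rmsd = average_pairwise_rmsd(rows, structures),
                 fingerprint = fingerprint, perc = NA_real_),
            class = "motif_alignment")
}

#' @export
print.motif_alignment <- function(x, ...) {
  cat(sprintf("Local structural alignment: %d structures x %d residues, avg RMSD %.3f A\n",
              nrow(x$rows), ncol(x$rows), x$rmsd))
  if (!is.na(x$fingerprint)) cat("  fingerprint:", x$fingerprint, "\n")
  for (i in seq_len(nrow(x$resno)))
    cat(sprintf("  %-12s %s\n", rownames(x$resno)[i],
                paste(x$resno[i, ], collapse = " ")))
  invisible(x)
}

#' Rank alignments by average pairwise RMSD
#'
#' Stable ascending sort: ties keep discovery order.
#'
#' @param alignments List of alignment records (class
#'   \code{"motif_alignment"}).
#' @return The list reordered by non-decreasing \code{rmsd}.
#' @export
sort_alignments <- function(alignments) {
  if (length(alignments) == 0L) return(alignments)
  sc <- vapply(alignments, `[[`, numeric(1), "rmsd")
  alignments[order(sc)]  # order() is a stable sort
}

#' Overlap of an alignment against previously kept alignments
#'
#' For each structure row, the percentage of its residues already observed
#' in the same structure's row of any kept alignment; the alignment's
#' overlap is the mean over rows. Residues are matched by structure identity
#' and residue index, not by column position.
#'
#' @param al Alignment record.
#' @param kept List of previously kept alignment records (may be empty).
#' @return Percentage in [0, 100].
#' @export
overlap_percentage <- function(al, kept) {
  if (length(kept) == 0L) return(0)
  ids <- rownames(al$rows)
  per_row <- vapply(seq_len(nrow(al$rows)), function(k) {
    seen <- unlist(lapply(kept, function(p) {
      r <- match(ids[k], rownames(p$rows))
      if (is.na(r)) stop("structure mismatch between alignments")
      p$rows[r, ]
    }))
    100 * mean(al$rows[k, ] %in% seen)
  }, numeric(1))
  mean(per_row)
}

#' Greedy overlap filter over a ranked alignment list
#'
#' Scans in rank order and keeps an alignment iff its
#' \code{\link{overlap_percentage}} against the already-kept set does not
#' exceed the threshold (strictly above discards). A threshold of 100
#' disables filtering. The kept records carry their overlap value in
#' \code{$perc}.
#'
#' @param ranked List of alignment records sorted by
#'   \code{\link{sort_alignments}}.
#' @param threshold Percentage in [0, 100].
#' @return Filtered list.
#' @export
filter_overlapping <- function(ranked, threshold) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 100)
    stop("threshold must lie in [0, 100]")
  kept <- list()
  for (al in ranked) {
    p <- overlap_percentage(al, kept)
    if (p <= threshold) {
      al$perc <- p
      kept[[length(kept) + 1L]] <- al
    }
  }
  kept
}

#' Query motif coverage of a reported row
#'
#' The percentage of a reference motif's residues recovered in the reported
#' row of the query structure.
#'
#' @param reported Vector of residue identifiers in the reported row.
#' @param query_motif Non-empty vector of the reference motif's residue
#'   identifiers (same identifier convention as \code{reported}).
#' @return Percentage in [0, 100].
#' @export
query_motif_coverage <- function(reported, query_motif) {
  if (length(query_motif) == 0L) stop("query motif is empty")
  100 * length(intersect(reported, query_motif)) / length(unique(query_motif))
}

# ---- report writers ------------------------------------------------------

.alignment_table <- function(alignments) {
  if (length(alignments) == 0L)
    return(data.frame(rank = integer(0), fingerprint = character(0),
                      avg_rmsd = numeric(0), perc_overlap = numeric(0),
                      motifs = character(0)))
  data.frame(
    rank = seq_along(alignments),
    fingerprint = vapply(alignments, `[[`, character(1), "fingerprint"),
    avg_rmsd = vapply(alignments, `[[`, numeric(1), "rmsd"),
    perc_overlap = vapply(alignments, `[[`, numeric(1), "perc"),
    motifs = vapply(alignments, function(a)
      paste(sprintf("%s:%s", rownames(a$resno),
                    apply(a$resno, 1, paste, collapse = ",")),
            collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}

#' Write alignments as a TSV report
#'
#' One row per alignment: rank, fingerprint, average RMSD, overlap
#' percentage, and the per-structure residue numbers as
#' \code{id:r1,r2,...;id2:...}.
#'
#' @param alignments List of alignment records.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_alignments_tsv <- function(alignments, file) {
  tab <- .alignment_table(alignments)
  tab$avg_rmsd <- sprintf("%.6f", tab$avg_rmsd)
  tab$perc_overlap <- sprintf("%.2f", tab$perc_overlap)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write alignments as a JSON report
#'
#' Full nested records: per alignment the fingerprint, average RMSD, overlap
#' percentage and per-structure residue numbers and internal indices.
#'
#' @inheritParams write_alignments_tsv
#' @export
write_alignments_json <- function(alignments, file) {
  recs <- lapply(seq_along(alignments), function(i) {
    a <- alignments[[i]]
    list(rank = i, fingerprint = a$fingerprint, avg_rmsd = a$rmsd,
         perc_overlap = a$perc,
         structures = lapply(seq_len(nrow(a$resno)), function(k)
           list(id = rownames(a$resno)[k],
                resno = as.integer(a$resno[k, ]),
                index = as.integer(a$rows[k, ]))))
  })
  jsonlite::write_json(recs, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Write aligned motif sequences as multi-FASTA
#'
#' One record per structure per alignment; headers carry the structure id,
#' alignment rank and residue numbers.
#'
#' @inheritParams write_alignments_tsv
#' @param structures List of \code{\link{calpha_structure}} objects the
#'   alignments refer to (for residue symbols).
#' @export
write_alignments_fasta <- function(alignments, structures, file) {
  ids <- vapply(structures, `[[`, character(1), "id")
  out <- character(0)
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    for (k in seq_len(nrow(a$rows))) {
      s <- structures[[match(rownames(a$rows)[k], ids)]]
      out <- c(out,
               sprintf(">%s|rank=%d|res=%s", s$id, i,
                       paste(a$resno[k, ], collapse = ",")),
               paste(s$symbols[a$rows[k, ]], collapse = ""))
    }
  }
  writeLines(out, file)
  invisible(file)
}
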