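# Independent brute-force oracles and fixture builders shared by the suite.
# Every oracle here is a plain-loop reimplementation kept deliberately
# separate from the package's vectorised/log-space code paths.

# strip every attribute except dim (bootstrap rows carry diagnostics)
bare_rows <- function(m) matrix(as.integer(m), nrow(m), ncol(m))

# ---- geometry builders ---------------------------------------------------

# 3 coplanar points with prescribed side lengths (d12, d13, d23)
triangle_coords <- function(sides) {
  a <- sides[1]; b <- sides[2]; cc <- sides[3]
  x <- (a^2 + b^2 - cc^2) / (2 * a)
  y2 <- b^2 - x^2
  stopifnot(y2 > 0)
  rbind(c(0, 0, 0), c(a, 0, 0), c(x, sqrt(y2), 0))
}

# random valid triangle with all sides in [3, 9] (10 A clique feasible);
# `avoid` lists side triples the new triangle must stay >= `margin` away
# from (Euclidean in side space), so decoys cannot mimic the planted seed or
# one another and the planted combination stays the unique consistent signal
random_triangle_sides <- function(avoid = list(), margin = 1.0) {
  repeat {
    s <- runif(3, 3, 9)
    if (!(s[1] + s[2] > s[3] && s[1] + s[3] > s[2] && s[2] + s[3] > s[1] &&
          abs((s[1]^2 + s[2]^2 - s[3]^2) / (2 * s[1])) < s[2] - 1e-3))
      next
    clash <- any(vapply(avoid, function(a) sqrt(sum((s - a)^2)) < margin,
                        logical(1)))
    if (!clash) return(s)
  }
}

# structure made of isolated 3-residue clusters spaced 60 A apart; each
# cluster matches the fingerprint "AAC" (symbols A, A, C in index order)
cluster_structure <- function(side_list, id) {
  xyz <- NULL
  symbols <- character(0)
  for (k in seq_along(side_list)) {
    tri <- triangle_coords(side_list[[k]])
    tri[, 1] <- tri[, 1] + 60 * (k - 1)
    xyz <- rbind(xyz, tri)
    symbols <- c(symbols, "A", "A", "C")
  }
  calpha_structure(id, symbols, xyz)
}

# bootstrap recovery fixture: each structure holds one planted triangle with
# identical internal geometry plus n_decoys random ones, at a random slot
make_seed_cluster_structures <- function(n_structures = 4, n_decoys = 5,
                                         planted_sides = c(4, 5, 6)) {
  structures <- vector("list", n_structures)
  planted_idx <- matrix(0L, n_structures, 3)
  seen <- list(planted_sides)
  for (i in seq_len(n_structures)) {
    slot <- sample.int(n_decoys + 1L, 1L)
    sides <- vector("list", n_decoys + 1L)
    for (k in seq_len(n_decoys + 1L)) {
      if (k == slot) {
        sides[[k]] <- planted_sides
      } else {
        sides[[k]] <- random_triangle_sides(avoid = seen)
        seen[[length(seen) + 1L]] <- sides[[k]]
      }
    }
    structures[[i]] <- cluster_structure(sides, sprintf("clust%02d", i))
    planted_idx[i, ] <- (3L * (slot - 1L)) + 1:3
  }
  list(structures = structures, planted = planted_idx)
}

# random compact structure for scoring property tests
random_box_structure <- function(n, id = "rand", box = 15) {
  calpha_structure(id, sample(amino_alphabet(), n, replace = TRUE),
                   matrix(runif(3 * n, 0, box), n, 3))
}

# ---- brute-force oracles -------------------------------------------------

oracle_pair_dist_seeds <- function(ia, sa, ib, sb) {
  p <- 1
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (pr in pairs) {
    da <- sqrt(sum((sa$xyz[ia[pr[1]], ] - sa$xyz[ia[pr[2]], ])^2))
    db <- sqrt(sum((sb$xyz[ib[pr[1]], ] - sb$xyz[ib[pr[2]], ])^2))
    p <- p * abs(da - db)
  }
  p
}

oracle_pairdist_profile <- function(x, j, ak, k, rows, structures) {
  p <- 1
  for (h in seq_len(ncol(rows))) {
    dj <- sqrt(sum((structures[[j]]$xyz[x, ] -
                      structures[[j]]$xyz[rows[j, h], ])^2))
    dk <- sqrt(sum((structures[[k]]$xyz[ak, ] -
                      structures[[k]]$xyz[rows[k, h], ])^2))
    p <- p * abs(dj - dk)
  }
  p
}

oracle_sim_dist <- function(x, candidates, j, rows, structures,
                            ffloor = 1e-6, pfloor = 1e-6) {
  tot <- 1
  for (k in seq_len(nrow(rows))) {
    if (k == j) next
    p <- 1
    for (h in seq_len(ncol(rows))) {
      dj <- sqrt(sum((structures[[j]]$xyz[x, ] -
                        structures[[j]]$xyz[rows[j, h], ])^2))
      dk <- sqrt(sum((structures[[k]]$xyz[candidates[k], ] -
                        structures[[k]]$xyz[rows[k, h], ])^2))
      p <- p * max(abs(dj - dk), ffloor)
    }
    tot <- tot * max(p, pfloor)
  }
  1 / tot
}

oracle_pair_dist_aligned <- function(rows, structures, i, j, k) {
  p <- 1
  for (h in seq_len(ncol(rows))) {
    if (h == k) next
    di <- sqrt(sum((structures[[i]]$xyz[rows[i, k], ] -
                      structures[[i]]$xyz[rows[i, h], ])^2))
    dj <- sqrt(sum((structures[[j]]$xyz[rows[j, k], ] -
                      structures[[j]]$xyz[rows[j, h], ])^2))
    p <- p * abs(di - dj)
  }
  p
}

oracle_badness <- function(rows, structures, k) {
  tot <- 0
  n <- nrow(rows)
  for (i in seq_len(n - 1))
    for (j in seq.int(i + 1, n))
      tot <- tot + oracle_pair_dist_aligned(rows, structures, i, j, k)
  tot
}

# cubic enumeration of feasible seed triples (unordered convention)
oracle_seed_triples <- function(s, fingerprint, radius = 10) {
  key <- paste(sort(strsplit(fingerprint, "")[[1]]), collapse = "")
  n <- length(s$symbols)
  out <- list()
  for (i in seq_len(n))
    for (j in seq_len(n))
      for (k in seq_len(n)) {
        if (!(i < j && j < k)) next
        if (s$dist[i, j] >= radius || s$dist[i, k] >= radius ||
            s$dist[j, k] >= radius) next
        if (paste(sort(s$symbols[c(i, j, k)]), collapse = "") != key) next
        out[[length(out) + 1L]] <- c(i, j, k)
      }
  if (length(out) == 0L) return(matrix(integer(0), 0, 3))
  do.call(rbind, out)
}

# exhaustive minimisation of the total seed pair-distance over one candidate
# combination per structure
oracle_best_combination <- function(cand_list, structures) {
  n <- length(cand_list)
  counts <- vapply(cand_list, nrow, integer(1))
  grid <- do.call(expand.grid, lapply(counts, seq_len))
  best <- NULL; best_val <- Inf
  for (r in seq_len(nrow(grid))) {
    sel <- as.integer(grid[r, ])
    tot <- 0
    for (i in seq_len(n - 1))
      for (j in seq.int(i + 1, n))
        tot <- tot + oracle_pair_dist_seeds(cand_list[[i]][sel[i], ],
                                            structures[[i]],
                                            cand_list[[j]][sel[j], ],
                                            structures[[j]])
    if (tot < best_val) { best_val <- tot; best <- sel }
  }
  list(selection = best, value = best_val)
}

# minimal fixed-column PDB ATOM text for CA-only test inputs
pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          altloc = " ", type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          type, serial, paste0(" ", elety), altloc, resid, chain, resno,
          x, y, z)
}
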