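# Ligand chemistry as plain molecular graphs: element-labelled atoms and
# heavy-atom bonds inferred from interatomic distances.  Bond orders,
# aromaticity and protonation are deliberately out of scope -- HETATM
# records do not carry them reliably.

# single-bond covalent radii (A) for the elements that occur in PDB ligands
.covalent_radii <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  SI = 1.11, P = 1.07, S = 1.05, CL = 1.02, SE = 1.20, BR = 1.20, I = 1.39
)

#' Build a molecular graph from an atom table
#'
#' @param elements character vector of element symbols.
#' @param bonds two-column integer matrix of undirected heavy-atom bonds
#'   (may have zero rows).
#' @param coords optional n x 3 coordinate matrix.
#' @return an object of class `molecule_graph`.
#' @export
molecule_graph <- function(elements, bonds = matrix(integer(0), 0, 2),
                           coords = NULL) {
  elements <- toupper(as.character(elements))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1) || any(bonds > length(elements)))
      .stopf("bond indices out of range")
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds[bonds[, 1] != bonds[, 2], , drop = FALSE])
  }
  structure(list(elements = elements, bonds = bonds, coords = coords),
            class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("molecule_graph: %d atoms (%s), %d bonds\n",
              length(x$elements),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    collapse = ","),
              nrow(x$bonds)))
  invisible(x)
}

.adjacency_list <- function(mol) {
  n <- length(mol$elements)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

#' Perceive a molecular graph from ligand coordinates
#'
#' Bonds are inferred wherever the interatomic distance does not exceed
#' 1.15 times the sum of single-bond covalent radii.  A disconnected graph
#' is returned as-is (with a message); overlapping atoms are an error.
#'
#' @param ligand a ligand as stored on a `complex_record` (list with an
#'   `atoms` data frame carrying `element`, `x`, `y`, `z`), or such a data
#'   frame directly.
#' @param tolerance multiplicative slack on the covalent-radius sum.
#' @param verbose message when the graph is disconnected.
#' @return a `molecule_graph` with coordinates attached.
#' @export
perceive_molecule <- function(ligand, tolerance = 1.15, verbose = FALSE) {
  atoms <- if (is.data.frame(ligand)) ligand else ligand$atoms
  if (is.null(atoms) || nrow(atoms) == 0) .stopf("ligand has no atoms")
  el <- toupper(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  bonds <- matrix(integer(0), 0, 2)
  if (n > 1) {
    d <- .cross_dist(xyz, xyz)
    if (any(d[upper.tri(d)] < 0.5)) .stopf("overlapping atoms (< 0.5 A apart)")
    r <- .covalent_radii[el]
    r[is.na(r)] <- 0.77
    lim <- outer(r, r, "+") * tolerance
    hit <- which(upper.tri(d) & d <= lim, arr.ind = TRUE)
    bonds <- hit
  }
  mol <- molecule_graph(el, bonds, coords = xyz)
  comps <- .graph_components(mol)
  if (max(comps) > 1) {
    .msgf(verbose, "perceived molecule is disconnected (%d components)",
          max(comps))
  }
  mol
}

.graph_components <- function(mol) {
  n <- length(mol$elements)
  adj <- .adjacency_list(mol)
  comp <- integer(n)
  cur <- 0
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1
    stack <- s
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]][comp[adj[[v]]] == 0])
    }
  }
  comp
}

# deterministic, platform-independent string hash into [0, nbits)
.path_hash <- function(s, nbits) {
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 33554393
  h %% nbits
}

#' Hashed linear-path fingerprint
#'
#' Enumerates every simple linear path of 1 to `max_len` atoms, encodes it
#' as its element sequence (canonicalised to the lexicographically smaller
#' reading direction) and hashes it onto a fixed-length bit vector.  The
#' hash is arithmetic-only and therefore identical across platforms.
#'
#' @param mol a `molecule_graph`.
#' @param nbits fingerprint length (1024 bits by default).
#' @param max_len maximum path length in atoms.
#' @return logical vector of length `nbits` with class `fingerprint`.
#' @export
path_fingerprint <- function(mol, nbits = 1024, max_len = 7) {
  adj <- .adjacency_list(mol)
  el <- mol$elements
  paths <- new.env(parent = emptyenv())
  walk <- function(path) {
    fwd <- paste(el[path], collapse = "-")
    rev_ <- paste(rev(el[path]), collapse = "-")
    assign(if (fwd <= rev_) fwd else rev_, TRUE, envir = paths)
    if (length(path) == max_len) return(invisible())
    for (nb in adj[[path[length(path)]]]) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  for (s in seq_along(el)) walk(s)
  bits <- rep(FALSE, nbits)
  for (p in ls(paths)) bits[.path_hash(p, nbits) + 1] <- TRUE
  structure(bits, class = "fingerprint")
}

#' Tanimoto coefficient of two fingerprints
#'
#' `|a AND b| / |a OR b|`, with the convention that two empty fingerprints
#' have similarity 0.
#'
#' @param a,b logical bit vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) .stopf("fingerprint length mismatch (%d vs %d)",
                                     length(a), length(b))
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Maximum connected common substructure
#'
#' Backtracking search for the largest one-to-one atom mapping between two
#' molecular graphs such that matched atoms have identical elements,
#' matched bonds exist in both graphs, and the common subgraph is
#' connected.  The search is exact unless the time budget expires, in
#' which case the best mapping found so far is returned with
#' `truncated = TRUE`.
#'
#' @param molA,molB `molecule_graph` objects.
#' @param time_budget wall-clock budget in seconds.
#' @return an `atom_equivalence`: list with `pairs` (two-column matrix of
#'   atom indices, A then B), `size`, and `truncated`.
#' @export
mcs_atom_equivalence <- function(molA, molB, time_budget = 10) {
  nA <- length(molA$elements)
  nB <- length(molB$elements)
  if (nA == 0 || nB == 0) .stopf("empty molecule graph")
  adjA <- .adjacency_list(molA)
  adjB <- .adjacency_list(molB)
  elA <- molA$elements
  elB <- molB$elements
  ub_total <- min(nA, nB)
  deadline <- Sys.time() + time_budget

  best <- matrix(integer(0), 0, 2)
  truncated <- FALSE
  mapA <- integer(nA)  # 0 = unmapped, else index in B
  mapB <- integer(nB)

  extend <- function(size) {
    if (size > nrow(best)) best <<- cbind(which(mapA > 0), mapA[mapA > 0])
    if (nrow(best) >= ub_total) return(TRUE)   # cannot improve further
    if (Sys.time() > deadline) {
      truncated <<- TRUE
      return(TRUE)
    }
    if (size + min(sum(mapA == 0), sum(mapB == 0)) <= nrow(best)) return(FALSE)
    # frontier: unmapped atoms adjacent to the mapped core in both graphs
    # through the same mapped pair (keeps the common subgraph connected)
    cands <- list()
    for (a in which(mapA > 0)) {
      b <- mapA[a]
      for (a2 in adjA[[a]]) {
        if (mapA[a2] != 0) next
        for (b2 in adjB[[b]]) {
          if (mapB[b2] != 0) next
          if (elA[a2] == elB[b2]) cands[[length(cands) + 1]] <- c(a2, b2)
        }
      }
    }
    if (length(cands) == 0) return(FALSE)
    # branch on one frontier atom of A: either map it to one of its
    # candidate partners or exclude it from the mapping entirely
    cand_mat <- unique(do.call(rbind, cands))
    a_star <- cand_mat[1, 1]
    partners <- cand_mat[cand_mat[, 1] == a_star, 2]
    for (b2 in partners) {
      mapA[a_star] <<- b2
      mapB[b2] <<- a_star
      done <- extend(size + 1)
      mapA[a_star] <<- 0L
      mapB[b2] <<- 0L
      if (done) return(TRUE)
    }
    # exclude a_star: mark it unusable for this subtree
    mapA[a_star] <<- -1L
    done <- extend(size)
    mapA[a_star] <<- 0L
    done
  }

  # seed pairs: group by element, rarest elements first to cut symmetry
  seed_el <- intersect(unique(elA), unique(elB))
  seed_el <- seed_el[order(vapply(seed_el, function(e)
    sum(elA == e) * sum(elB == e), numeric(1)))]
  for (e in seed_el) {
    if (nrow(best) >= ub_total || truncated) break
    aset <- which(elA == e)
    for (a in aset) {
      for (b in which(elB == e)) {
        mapA[] <- 0L
        mapB[] <- 0L
        mapA[a] <- b
        mapB[b] <- a
        if (extend(1L)) break
      }
      if (nrow(best) >= ub_total || truncated) break
    }
  }
  structure(list(pairs = best, size = nrow(best), truncated = truncated),
            class = "atom_equivalence")
}

#' Identity atom equivalence
#'
#' @param n atom count.
#' @return an `atom_equivalence` mapping atom i to atom i.
#' @export
identity_equivalence <- function(n) {
  structure(list(pairs = cbind(seq_len(n), seq_len(n)), size = n,
                 truncated = FALSE),
            class = "atom_equivalence")
}

#' @export
print.atom_equivalence <- function(x, ...) {
  cat(sprintf("atom_equivalence: %d matched atom pair(s)%s\n", x$size,
              if (x$truncated) " [search truncated]" else ""))
  invisible(x)
}

#' Leader clustering of molecules by fingerprint similarity
#'
#' Molecules are processed in order of decreasing heavy-atom count (ties
#' keep input order); each joins the earliest-founded cluster whose
#' representative has Tanimoto similarity at or above the threshold,
#' otherwise it founds a new cluster.  Fully deterministic.
#'
#' @param mols list of `molecule_graph` objects.
#' @param threshold Tanimoto threshold for joining a cluster.
#' @param fingerprints optional precomputed list of fingerprints.
#' @return list with `assignment` (integer cluster id per input molecule),
#'   `representatives` (input indices of cluster representatives), and
#'   `n_clusters`.
#' @export
leader_cluster <- function(mols, threshold = 0.7, fingerprints = NULL) {
  n <- length(mols)
  if (n == 0) {
    return(list(assignment = integer(0), representatives = integer(0),
                n_clusters = 0L))
  }
  if (is.null(fingerprints)) fingerprints <- lapply(mols, path_fingerprint)
  sizes <- vapply(mols, function(m) length(m$elements), numeric(1))
  ord <- order(-sizes, seq_len(n))
  assignment <- integer(n)
  reps <- integer(0)
  for (i in ord) {
    joined <- FALSE
    for (ci in seq_along(reps)) {
      if (tanimoto(fingerprints[[i]], fingerprints[[reps[ci]]]) >= threshold) {
        assignment[i] <- ci
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      assignment[i] <- length(reps)
    }
  }
  list(assignment = assignment, representatives = reps,
       n_clusters = length(reps))
}

#' Serialise a fingerprint as a hex string
#'
#' @param fp a `fingerprint` (logical vector, length divisible by 4).
#' @return single hex string.
#' @export
fingerprint_to_hex <- function(fp) {
  nib <- matrix(as.integer(fp), nrow = 4)
  paste(sprintf("%x", colSums(nib * c(8, 4, 2, 1))), collapse = "")
}

#' @rdname fingerprint_to_hex
#' @param hex hex string from [fingerprint_to_hex()].
#' @export
hex_to_fingerprint <- function(hex) {
  vals <- strtoi(strsplit(hex, "")[[1]], 16L)
  bits <- as.logical(unlist(lapply(vals, function(v)
    bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0)))
  structure(bits, class = "fingerprint")
}
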