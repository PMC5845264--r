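# Rigid-body least-squares superposition and the alignment-quality
# geometry built on it: reference alignments induced by superposing the
# two bound ligands, and the ligand RMSD of an arbitrary pocket alignment.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping point set B onto
#' point set A, via SVD of the cross-covariance matrix with the standard
#' determinant sign correction (no reflections).
#'
#' @param coordsA,coordsB n x 3 matrices, equal n >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length-3 vector),
#'   `rmsd` over the fitted points, and `n_fitted`; class
#'   `superposition_result`.  The fitted position of a point `b` is
#'   `rotation %*% b + translation`.
#' @export
kabsch_fit <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA)
  B <- as.matrix(coordsB)
  if (nrow(A) != nrow(B)) .stopf("coordinate sets differ in size")
  if (nrow(A) < 3) .stopf("need at least 3 points, got %d", nrow(A))
  if (any(!is.finite(A)) || any(!is.finite(B))) .stopf("non-finite coordinates")
  ca <- colMeans(A)
  cb <- colMeans(B)
  Ac <- sweep(A, 2, ca)
  Bc <- sweep(B, 2, cb)
  if (svd(Ac)$d[2] < 1e-9 || svd(Bc)$d[2] < 1e-9) {
    .stopf("degenerate (collinear) point set")
  }
  H <- crossprod(Bc, Ac)          # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Ac)^2)))
  structure(list(rotation = R, translation = as.numeric(ca - R %*% cb),
                 rmsd = rmsd, n_fitted = nrow(A)),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition_result: rmsd %.3f A over %d points\n",
              x$rmsd, x$n_fitted))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param fit a `superposition_result` (or list with `rotation` and
#'   `translation`).
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(fit, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Construct a pocket alignment object
#'
#' An ordered set of one-to-one residue correspondences between two
#' pockets.  Residues are identified by (chain, author residue number,
#' insertion code).
#'
#' @param pairs data frame with columns chainA, resA, icodeA, chainB,
#'   resB, icodeB.
#' @param method method tag (`reference`, `apoc`, `siteengine`, `glosa`,
#'   or `other`).
#' @param score method score, or `NA`.
#' @param ... further attributes stored on the object (e.g. `ligand_rmsd`).
#' @return object of class `pocket_alignment`.
#' @export
pocket_alignment <- function(pairs, method = "other", score = NA_real_, ...) {
  need <- c("chainA", "resA", "icodeA", "chainB", "resB", "icodeB")
  if (!all(need %in% names(pairs))) {
    .stopf("alignment pairs need columns: %s", paste(need, collapse = ", "))
  }
  keyA <- paste(pairs$chainA, pairs$resA, pairs$icodeA)
  keyB <- paste(pairs$chainB, pairs$resB, pairs$icodeB)
  if (anyDuplicated(keyA) || anyDuplicated(keyB)) {
    .stopf("alignment is not one-to-one")
  }
  structure(list(pairs = pairs, method = method, score = score, ...),
            class = "pocket_alignment")
}

#' @export
print.pocket_alignment <- function(x, ...) {
  cat(sprintf("pocket_alignment [%s]: %d residue pair(s), score %s\n",
              x$method, nrow(x$pairs),
              if (is.na(x$score)) "NA" else format(x$score)))
  invisible(x)
}

.record_ca <- function(record) {
  ca <- record$chain_atoms
  ca[ca$name == "CA", , drop = FALSE]
}

.lookup_ca_coords <- function(record, chain, resno, icode) {
  ca <- .record_ca(record)
  idx <- match(.residue_key(chain, resno, icode),
               .residue_key(ca$chain, ca$resno, ca$icode))
  if (anyNA(idx)) {
    .stopf("%d residue(s) of the alignment lack a CA atom in record %s",
           sum(is.na(idx)), record$id)
  }
  as.matrix(ca[idx, c("x", "y", "z")])
}

#' Reference alignment from ligand superposition
#'
#' Superposes complex B onto complex A using the equivalenced ligand heavy
#' atoms, then pairs binding residues one-to-one by minimum-total-cost
#' assignment over Calpha-Calpha distances, admitting only pairs at or
#' below `pair_cutoff`.  The ligand RMSD over the equivalenced atoms after
#' the ligand superposition is recorded on the result.
#'
#' @param recA,recB `complex_record` objects.
#' @param eq an `atom_equivalence` mapping ligand A atoms to ligand B
#'   atoms (at least 3 pairs).
#' @param pair_cutoff admissibility cutoff (A) for residue pairs.
#' @return a `pocket_alignment` with method `reference`, attributes
#'   `ligand_rmsd` (A) and `empty` flag.
#' @export
reference_alignment <- function(recA, recB, eq, pair_cutoff = 5.0) {
  if (eq$size < 3) .stopf("need >= 3 equivalenced ligand atoms, got %d", eq$size)
  ligA <- as.matrix(recA$ligand$atoms[eq$pairs[, 1], c("x", "y", "z")])
  ligB <- as.matrix(recB$ligand$atoms[eq$pairs[, 2], c("x", "y", "z")])
  fit <- kabsch_fit(ligA, ligB)

  bA <- recA$binding_residues
  bB <- recB$binding_residues
  caA <- .lookup_ca_coords(recA, bA$chain, bA$resno, bA$icode)
  caB <- apply_transform(fit, .lookup_ca_coords(recB, bB$chain, bB$resno, bB$icode))
  d <- .cross_dist(caA, caB)
  big <- 1e6
  cost <- ifelse(d <= pair_cutoff, d, big)
  asg <- solve_assignment(cost)
  keep <- which(!is.na(asg) & cost[cbind(seq_along(asg), asg)] < big / 2)
  pairs <- data.frame(
    chainA = bA$chain[keep], resA = bA$resno[keep], icodeA = bA$icode[keep],
    chainB = bB$chain[asg[keep]], resB = bB$resno[asg[keep]],
    icodeB = bB$icode[asg[keep]],
    stringsAsFactors = FALSE
  )
  # order by sequence position in A
  posA <- match(.residue_key(pairs$chainA, pairs$resA, pairs$icodeA),
                .residue_key(recA$residues$chain, recA$residues$resno,
                             recA$residues$icode))
  pairs <- pairs[order(posA), , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0) {
    warning("no admissible residue pairs; empty reference alignment")
  }
  pocket_alignment(pairs, method = "reference", score = NA_real_,
                   ligand_rmsd = fit$rmsd, empty = nrow(pairs) == 0)
}

#' Ligand RMSD of a pocket alignment
#'
#' Superposes complex B onto complex A using the Calpha atoms of the
#' aligned binding residues, then returns the RMSD over the equivalenced
#' ligand heavy atoms.  Low values mean the alignment places the two
#' ligands on top of each other, i.e. is geometrically correct.
#'
#' @param aln a `pocket_alignment` with at least 3 pairs.
#' @param recA,recB `complex_record` objects.
#' @param eq `atom_equivalence` between the two ligands.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd_of_alignment <- function(aln, recA, recB, eq) {
  p <- aln$pairs
  if (nrow(p) < 3) {
    .stopf("alignment has %d usable pair(s); need at least 3", nrow(p))
  }
  caA <- .lookup_ca_coords(recA, p$chainA, p$resA, p$icodeA)
  caB <- .lookup_ca_coords(recB, p$chainB, p$resB, p$icodeB)
  fit <- kabsch_fit(caA, caB)
  ligA <- as.matrix(recA$ligand$atoms[eq$pairs[, 1], c("x", "y", "z")])
  ligB <- apply_transform(fit, as.matrix(
    recB$ligand$atoms[eq$pairs[, 2], c("x", "y", "z")]))
  sqrt(mean(rowSums((ligA - ligB)^2)))
}

#' Write / read a pocket alignment as TSV
#'
#' The header line carries the method tag and score as a comment so a
#' round trip preserves them.
#'
#' @param aln a `pocket_alignment`.
#' @param path file path.
#' @return `path` (write) or a `pocket_alignment` (read).
#' @export
write_alignment_tsv <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s score=%s", aln$method,
                     ifelse(is.na(aln$score), "NA", format(aln$score, digits = 12))),
             con)
  utils::write.table(aln$pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment_tsv
#' @export
read_alignment_tsv <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec("# method=(\\S+) score=(\\S+)", header))[[1]]
  if (length(m) != 3) .stopf("malformed alignment header: %s", header)
  pairs <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "integer", "character",
                                            "character", "integer", "character"),
                             na.strings = NULL)
  pairs$icodeA[is.na(pairs$icodeA)] <- ""
  pairs$icodeB[is.na(pairs$icodeB)] <- ""
  pocket_alignment(pairs, method = m[2],
                   score = suppressWarnings(as.numeric(m[3])))
}
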