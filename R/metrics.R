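# Scalar statistics of pocket similarity and alignment quality.
#
# SSC (Szymkiewicz-Simpson coefficient): overlap of two typed
#   ligand-protein contact lists, |A n B| / min(|A|, |B|), where two
#   contacts match iff their ligand atoms are chemically equivalent and
#   their residues fall in the same group (I-VIII).
# Kendall tau: ordinal association of an alignment's residue order in the
#   two protein sequences, (nC - nD) / (n (n - 1) / 2); 1 for sequential
#   alignments, -1 when one side is reversed, ~0 for sequence
#   order-independent alignments.  No tie correction: within one chain a
#   sequence position cannot repeat.
# Spearman rho: rank correlation of compound rankings from virtual
#   screening against two targets, 1 - 6 sum(d_i^2) / (n (n^2 - 1)).

#' Szymkiewicz-Simpson overlap of two contact profiles
#'
#' Counts the intersection of two typed contact lists as a maximum
#' one-to-one matching: a contact in A can match a contact in B only if
#' the ligand atoms correspond under `eq` and the residue groups are
#' identical.  Returns `|A n B| / min(|A|, |B|)`.
#'
#' @param profileA,profileB contact data frames from [contact_profile()].
#' @param eq `atom_equivalence` mapping ligand A atoms to ligand B atoms.
#' @return overlap coefficient in `[0, 1]`.
#' @export
ssc <- function(profileA, profileB, eq) {
  nA <- nrow(profileA)
  nB <- nrow(profileB)
  if (nA == 0 && nB == 0) .stopf("both contact profiles are empty")
  if (nA == 0 || nB == 0) return(0)
  a2b <- integer(0)
  a2b[eq$pairs[, 1]] <- eq$pairs[, 2]
  mappedB <- a2b[profileA$ligand_atom]
  edges <- which(
    outer(seq_len(nA), seq_len(nB), function(i, j)
      !is.na(mappedB[i]) & mappedB[i] == profileB$ligand_atom[j] &
        profileA$group[i] == profileB$group[j]),
    arr.ind = TRUE)
  if (nrow(edges) == 0) return(0)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nA), rep(TRUE, nB)),
    edges = as.vector(t(cbind(edges[, 1], nA + edges[, 2]))))
  m <- igraph::max_bipartite_match(g)
  m$matching_size / min(nA, nB)
}

#' Kendall tau of a pocket alignment
#'
#' Sorts the aligned residue pairs by sequence position in pocket A and
#' counts, over all position pairs, how many keep the same order in
#' pocket B (concordant) versus invert it (discordant);
#' `tau = (nC - nD) / (n (n - 1) / 2)`.
#'
#' @param aln either a `pocket_alignment` (then `recA`/`recB` are needed
#'   to resolve sequence positions) or a data frame / list with numeric
#'   `posA` and `posB` sequence positions.
#' @param recA,recB `complex_record` objects, required when `aln` is a
#'   `pocket_alignment`.
#' @return an `order_statistics` list: `n_C`, `n_D`, `n`, `tau`.
#' @export
kendall_tau <- function(aln, recA = NULL, recB = NULL) {
  if (inherits(aln, "pocket_alignment")) {
    if (is.null(recA) || is.null(recB)) {
      .stopf("recA and recB are required to resolve sequence positions")
    }
    p <- aln$pairs
    posA <- match(.residue_key(p$chainA, p$resA, p$icodeA),
                  .residue_key(recA$residues$chain, recA$residues$resno,
                               recA$residues$icode))
    posB <- match(.residue_key(p$chainB, p$resB, p$icodeB),
                  .residue_key(recB$residues$chain, recB$residues$resno,
                               recB$residues$icode))
    if (anyNA(posA) || anyNA(posB)) .stopf("unresolvable residue in alignment")
  } else {
    posA <- aln$posA
    posB <- aln$posB
  }
  n <- length(posA)
  if (n < 2) .stopf("alignment must have at least 2 pairs, got %d", n)
  b <- posB[order(posA)]
  # d[i, j] = b[j] - b[i] for i < j: positive = concordant pair
  d <- -outer(b, b, "-")
  ut <- upper.tri(d)
  n_c <- sum(d[ut] > 0)
  n_d <- sum(d[ut] < 0)
  structure(list(n_C = n_c, n_D = n_d, n = n,
                 tau = (n_c - n_d) / (n * (n - 1) / 2)),
            class = "order_statistics")
}

#' @export
print.order_statistics <- function(x, ...) {
  cat(sprintf("order_statistics: n=%d, nC=%d, nD=%d, tau=%.4f\n",
              x$n, x$n_C, x$n_D, x$tau))
  invisible(x)
}

#' Per-target rank vector from screening scores
#'
#' Ranks compounds best-affinity-first: rank 1 is the most negative
#' predicted binding energy.  Ties receive midranks.
#'
#' @param target_id target (pocket) identifier.
#' @param values named numeric vector of per-compound scores (lower =
#'   better affinity).
#' @return object of class `rank_vector` with `target_id`, `compound_ids`,
#'   `values`, `ranks`, `n`.
#' @export
rank_vector <- function(target_id, values) {
  if (anyDuplicated(names(values))) .stopf("duplicate compound id")
  structure(list(target_id = target_id, compound_ids = names(values),
                 values = unname(values), ranks = unname(.midrank(values)),
                 n = length(values)),
            class = "rank_vector")
}

#' @export
print.rank_vector <- function(x, ...) {
  cat(sprintf("rank_vector [%s]: %d compounds\n", x$target_id, x$n))
  invisible(x)
}

#' Spearman rank correlation of two screening rankings
#'
#' Without ties this is exactly `1 - 6 sum(d_i^2) / (n (n^2 - 1))` where
#' `d_i` is the rank difference of compound i between the two targets.
#' With ties (docking scores do tie) midranks are used and the statistic
#' is the Pearson correlation of the midranks, of which the classic
#' formula is the tie-free special case.
#'
#' @param a,b `rank_vector` objects (same compounds, same order) or plain
#'   numeric vectors of scores.
#' @return correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(a, b) {
  va <- if (inherits(a, "rank_vector")) a$values else as.numeric(a)
  vb <- if (inherits(b, "rank_vector")) b$values else as.numeric(b)
  if (length(va) != length(vb)) .stopf("rank vectors differ in length")
  n <- length(va)
  if (n < 3) .stopf("need at least 3 compounds, got %d", n)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    .stopf("constant score vector: correlation undefined")
  }
  ra <- .midrank(va)
  rb <- .midrank(vb)
  if (anyDuplicated(ra) || anyDuplicated(rb)) {
    return(stats::cor(ra, rb))
  }
  1 - 6 * sum((ra - rb)^2) / (n * (n^2 - 1))
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when any factor of the denominator is 0.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return MCC in `[-1, 1]`.
#' @export
binary_mcc <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) .stopf("negative confusion count")
  if (all(counts == 0)) .stopf("all confusion counts are zero")
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' MCC of a pocket alignment against a reference alignment
#'
#' Residue pairs are the classification units: TP are pairs present in
#' both alignments, FP pairs only in the test alignment, FN pairs only in
#' the reference, and TN the remaining `nA * nB` candidate pairs.
#'
#' @param test,reference `pocket_alignment` objects over the same pockets.
#' @param nA,nB number of binding residues in pocket A and B.
#' @return MCC in `[-1, 1]`.
#' @export
alignment_mcc <- function(test, reference, nA, nB) {
  if (nrow(reference$pairs) == 0) .stopf("empty reference alignment")
  keyify <- function(p) paste(p$chainA, p$resA, p$icodeA, "->",
                              p$chainB, p$resB, p$icodeB)
  kt <- keyify(test$pairs)
  kr <- keyify(reference$pairs)
  tp <- length(intersect(kt, kr))
  fp <- length(setdiff(kt, kr))
  fn <- length(setdiff(kr, kt))
  tn <- as.numeric(nA) * nB - tp - fp - fn
  binary_mcc(tp, fp, tn, fn)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) .stopf("series differ in length")
  if (length(x) < 3) .stopf("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) .stopf("constant input series")
  stats::cor(x, y)
}

#' Method score container
#'
#' @param method method tag (`apoc`, `siteengine`, `glosa`, `meta`, ...).
#' @param value score value.
#' @param significance optional p-value.
#' @return object of class `method_score`.
#' @export
method_score <- function(method, value, significance = NA_real_) {
  structure(list(method = method, value = value, significance = significance),
            class = "method_score")
}

#' @export
print.method_score <- function(x, ...) {
  cat(sprintf("method_score [%s]: %.4f%s\n", x$method, x$value,
              if (is.na(x$significance)) ""
              else sprintf(" (p=%.3g)", x$significance)))
  invisible(x)
}

#' Meta-predictor score
#'
#' Combines a direct pocket-alignment score with the indirect
#' virtual-screening signal by simple multiplication: the meta score is
#' the direct score times the Spearman rho of the two targets' compound
#' rankings.
#'
#' @param direct a `method_score` (direct alignment score).
#' @param rho Spearman correlation in `[-1, 1]`.
#' @return a `method_score` with method tag `meta`.
#' @export
meta_score <- function(direct, rho) {
  if (!inherits(direct, "method_score")) direct <- method_score("other", direct)
  if (is.na(direct$value)) .stopf("direct score value missing")
  if (abs(rho) > 1 + 1e-12) .stopf("rho outside [-1, 1]")
  method_score("meta", direct$value * rho)
}

#' Pair-level metrics for one pocket pair
#'
#' Convenience wrapper computing the full per-pair metric set used in
#' benchmark reports.
#'
#' @param recA,recB `complex_record` objects.
#' @param eq `atom_equivalence` between the ligands.
#' @param aln optional `pocket_alignment` to score (defaults to the
#'   reference alignment).
#' @param tm_score externally supplied global structure similarity.
#' @param pair_id identifier for the pair.
#' @return data frame with one row: pair_id, method, score, ssc, tau,
#'   ligand_rmsd, reference_ligand_rmsd, alignment_mcc, tm_score.
#' @export
pair_metrics <- function(recA, recB, eq, aln = NULL, tm_score = NA_real_,
                         pair_id = paste(recA$id, recB$id, sep = "|")) {
  ref <- reference_alignment(recA, recB, eq)
  if (is.null(aln)) aln <- ref
  tau <- kendall_tau(aln, recA, recB)
  data.frame(
    pair_id = pair_id,
    method = aln$method,
    score = aln$score,
    ssc = ssc(recA$contacts, recB$contacts, eq),
    tau = tau$tau,
    ligand_rmsd = ligand_rmsd_of_alignment(aln, recA, recB, eq),
    reference_ligand_rmsd = ref$ligand_rmsd,
    alignment_mcc = alignment_mcc(aln, ref, nrow(recA$binding_residues),
                                  nrow(recB$binding_residues)),
    tm_score = tm_score,
    stringsAsFactors = FALSE
  )
}

#' Pairwise Spearman correlation matrix of target rankings
#'
#' @param scores numeric matrix, compounds in rows, targets in columns.
#' @return symmetric matrix of Spearman correlations.
#' @export
spearman_matrix <- function(scores) {
  t_n <- ncol(scores)
  out <- diag(1, t_n)
  dimnames(out) <- list(colnames(scores), colnames(scores))
  if (t_n < 2) return(out)
  for (i in seq_len(t_n - 1)) {
    for (j in seq(i + 1, t_n)) {
      out[i, j] <- out[j, i] <- spearman_rho(scores[, i], scores[, j])
    }
  }
  out
}
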