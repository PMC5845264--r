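# Deterministic synthetic-data generators.  Each generator seeds the R
# random stream once from its `seed` argument, so identical calls are
# byte-identical; every planted ground truth is returned in
# machine-readable form so downstream tests are self-judging.
#
# Toy complexes are Calpha traces from a self-avoiding random walk with
# 3.8 A steps and a 3.5 A exclusion radius, one side-chain pseudo-atom
# (CB) per residue, and a ligand of single heavy atoms planted 3.7 A from
# the pocket residues' Calpha along the side-chain direction.  This
# emulates pocket geometry and contact typing, not protein energetics.

.unit <- function(v) v / sqrt(sum(v^2))

.random_unit <- function() .unit(stats::rnorm(3))

# self-avoiding walk: extends `fixed` (matrix of existing Calpha, may be
# NULL) by `n_new` steps of 3.8 A keeping every non-consecutive pair at
# least 3.5 A apart
.saw_extend <- function(fixed, n_new, step = 3.8, min_sep = 3.5,
                        max_tries = 200) {
  pts <- if (is.null(fixed)) matrix(stats::rnorm(3), 1, 3) else fixed
  n_have <- nrow(pts)
  goal <- n_have + n_new - if (is.null(fixed)) 0 else 0
  dir <- if (n_have > 1) .unit(pts[n_have, ] - pts[n_have - 1, ]) else .random_unit()
  while (nrow(pts) < n_have + n_new) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      # persistence: bias towards the previous direction opens the walk up
      cand_dir <- .unit(dir + 1.2 * .random_unit())
      cand <- pts[nrow(pts), ] + step * cand_dir
      prev <- pts[seq_len(nrow(pts) - 1), , drop = FALSE]
      if (nrow(prev) == 0 ||
          min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) {
        pts <- rbind(pts, cand)
        dir <- cand_dir
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  pts
}

.saw_chain <- function(n, fixed = NULL, restarts = 25) {
  for (r in seq_len(restarts)) {
    n_new <- n - if (is.null(fixed)) 1 else nrow(fixed)
    pts <- .saw_extend(fixed, n_new)
    if (!is.null(pts)) return(pts)
  }
  .stopf("self-avoiding walk infeasible after %d restarts; try a new seed",
         restarts)
}

# side-chain directions: perpendicular to the local backbone axis and
# parallel-transported along the chain, so consecutive side chains point
# to the same face and the ligand threaded past them stays clear of the
# backbone
.cb_directions <- function(ca) {
  n <- nrow(ca)
  u <- matrix(0, n, 3)
  prev <- .random_unit()
  for (i in seq_len(n)) {
    lo <- max(1, i - 1)
    hi <- min(n, i + 1)
    axis <- .unit(ca[hi, ] - ca[lo, ])
    v <- prev - sum(prev * axis) * axis
    if (sqrt(sum(v^2)) < 1e-6) {
      v <- .random_unit()
      v <- v - sum(v * axis) * axis
    }
    u[i, ] <- .unit(v)
    prev <- u[i, ]
  }
  u
}

# resample a piecewise-linear curve through `anchors` at m points
# equally spaced in arc length
.resample_curve <- function(anchors, m) {
  seg <- sqrt(rowSums(diff(anchors)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  targets <- seq(0, total, length.out = m)
  out <- matrix(0, m, 3)
  for (i in seq_len(m)) {
    j <- max(which(s <= targets[i] + 1e-12))
    if (j >= nrow(anchors)) {
      out[i, ] <- anchors[nrow(anchors), ]
    } else {
      f <- (targets[i] - s[j]) / seg[j]
      out[i, ] <- (1 - f) * anchors[j, ] + f * anchors[j + 1, ]
    }
  }
  out
}

.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.atom_df <- function(serial, name, element, xyz, chain, resno, icode, resname,
                     hetero) {
  data.frame(serial = serial, name = name, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, altloc = "", chain = chain, resno = resno,
             icode = icode, resname = resname, is_hetero = hetero,
             stringsAsFactors = FALSE)
}

# assemble a complex_record from generated geometry
.build_record <- function(pdb_id, chain_id, resnames, ca, cb, resno_start,
                          lig_elements, lig_xyz, lig_name = "LIG",
                          contact_cutoff = 4.5) {
  n <- nrow(ca)
  resno <- as.integer(seq(resno_start, length.out = n))
  chain_atoms <- rbind(
    .atom_df(seq_len(n) * 2 - 1, "CA", "C", ca, chain_id, resno, "", resnames, FALSE),
    .atom_df(seq_len(n) * 2, "CB", "C", cb, chain_id, resno, "", resnames, FALSE))
  chain_atoms <- chain_atoms[order(chain_atoms$serial), ]
  rownames(chain_atoms) <- NULL
  m <- nrow(lig_xyz)
  lig_atoms <- .atom_df(2 * n + seq_len(m),
                        paste0(lig_elements, seq_len(m)), lig_elements,
                        lig_xyz, chain_id, as.integer(resno_start + n + 10), "",
                        lig_name,
                        TRUE)
  res <- data.frame(chain = chain_id, resno = resno, icode = "",
                    resname = resnames, stringsAsFactors = FALSE)
  rec <- structure(list(
    id = sprintf("%s_%s_%s", pdb_id, chain_id, lig_name),
    pdb_id = pdb_id, chain_id = chain_id,
    residues = res, chain_atoms = chain_atoms,
    sequence = paste(.one_letter(resnames), collapse = ""),
    ligand = list(res_name = lig_name, atoms = lig_atoms,
                  parent_chain = chain_id),
    pocket_source = "ligand-derived"
  ), class = "complex_record")
  rec$contacts <- contact_profile(rec, cutoff = contact_cutoff)
  bk <- unique(rec$contacts[, c("chain", "resno", "icode", "resname")])
  rec$binding_residues <- bk[order(bk$resno), , drop = FALSE]
  rownames(rec$binding_residues) <- NULL
  rec
}

#' Serialise a complex record as PDB text
#'
#' Full chain (CA + CB pseudo-atoms for generated complexes) plus the
#' ligand as HETATM records; useful to exercise the PDB reader on
#' generated fixtures.
#'
#' @param record a `complex_record`.
#' @return character vector of PDB lines.
#' @export
complex_to_pdb_text <- function(record) {
  ca <- record$chain_atoms
  lig <- record$ligand$atoms
  lines <- character(0)
  for (i in seq_len(nrow(ca))) {
    lines <- c(lines, .pdb_atom_line("ATOM", ca$serial[i], ca$name[i],
                                     ca$resname[i], ca$chain[i], ca$resno[i],
                                     ca$icode[i], ca$x[i], ca$y[i], ca$z[i],
                                     element = ca$element[i]))
  }
  lines <- c(lines, "TER")
  for (i in seq_len(nrow(lig))) {
    lines <- c(lines, .pdb_atom_line("HETATM", lig$serial[i], lig$name[i],
                                     lig$resname[i], lig$chain[i], lig$resno[i],
                                     lig$icode[i], lig$x[i], lig$y[i], lig$z[i],
                                     element = lig$element[i]))
  }
  c(lines, "END")
}

.pocket_name_pool <- list(
  positive = c("LEU", "VAL", "GLU", "ASP", "SER", "HIS"),
  negativeA = c("LEU", "ILE", "GLU", "ASN"),   # groups I, VI
  negativeB = c("LYS", "ARG", "PHE", "HIS")    # groups VII, V, VIII
)
.other_names <- c("ALA", "GLY", "THR", "PRO", "TRP", "GLN", "MET", "TYR")

#' Generate a synthetic pocket pair with known ground truth
#'
#' Builds two toy protein-ligand complexes.  A `positive` pair shares a
#' congruent pocket: the pocket residues and ligand of complex A are
#' copied into complex B under a random rigid motion (plus optional
#' Gaussian coordinate noise) and the rest of chain B is regrown as an
#' independent self-avoiding walk, so the two chains fold differently but
#' carry the same binding micro-environment and an exactly known residue
#' mapping.  A `negative` pair has independently generated pockets whose
#' residue groups and ligand elements are disjoint.
#'
#' @param seed integer seed; identical seed and parameters give
#'   byte-identical output.
#' @param n_residues chain length (>= 50 for curation-grade fixtures;
#'   smaller is fine elsewhere).
#' @param n_pocket number of pocket residues; the planted ligand is a
#'   connected chain of `3 * n_pocket - 2` heavy atoms threaded along the
#'   pocket.
#' @param coordinate_noise Gaussian noise sd (A, per coordinate) added to
#'   complex B's pocket and ligand in a positive pair.
#' @param relation `"positive"` or `"negative"`.
#' @return list with `recA`, `recB` (`complex_record`s), `mapping` (the
#'   planted `pocket_alignment`, `NULL` for negative pairs), `eq` (ligand
#'   `atom_equivalence`), `relation`, `noise`, and `truth` (list with the
#'   generator's own contact enumeration per record).
#' @export
make_complex_pair <- function(seed, n_residues = 60, n_pocket = 6,
                              coordinate_noise = 0,
                              relation = c("positive", "negative")) {
  relation <- match.arg(relation)
  set.seed(seed)
  k <- n_pocket
  m <- 3 * k - 2   # ligand heavy-atom count (see build_half)

  build_half <- function(chain_id, resno_start, pocket_names, lig_elements,
                         fixed_pocket = NULL, other_pool = .other_names) {
    for (attempt in 1:60) {
      # pocket segment first (possibly prescribed), then the rest of the walk
      ca <- .saw_chain(n_residues, fixed = fixed_pocket)
      cb_dir <- .cb_directions(ca)
      if (!is.null(fixed_pocket)) {
        # keep the prescribed pocket side chains (first k rows) aligned with
        # the transplanted geometry
        cb_dir[seq_len(k), ] <- attr(fixed_pocket, "cb_dir")
      }
      cb <- ca + 1.5 * cb_dir
      # ligand: a connected chain of heavy atoms threaded along the pocket
      # at ~3.7 A from the backbone; 3k-2 atoms sampled uniformly in arc
      # length give bond-range spacing (~1.3 A) so perceive_molecule sees
      # one connected molecule
      anchors <- ca[seq_len(k), , drop = FALSE] +
        3.7 * cb_dir[seq_len(k), , drop = FALSE]
      lig_xyz <- .resample_curve(anchors, 3 * k - 2)
      # feasibility of the planted ligand:
      #  - non-covalent clearance (>= 2 A from every protein heavy atom,
      #    otherwise the complex is a covalent adduct downstream)
      #  - no self-overlap where the offset curve folds back on itself
      #  - consecutive atoms within carbon-carbon bond range
      dmin <- min(.cross_dist(lig_xyz, rbind(ca, cb)))
      dself <- .cross_dist(lig_xyz, lig_xyz)
      diag(dself) <- Inf
      steps <- sqrt(rowSums(diff(lig_xyz)^2))
      if (dmin >= 2.0 && min(dself) >= 0.8 && max(steps) <= 1.7) break
      if (attempt == 60) .stopf("ligand placement infeasible; try a new seed")
    }
    names_all <- c(pocket_names,
                   sample(other_pool, n_residues - k, replace = TRUE))
    list(ca = ca, cb = cb, cb_dir = cb_dir, lig_xyz = lig_xyz,
         resnames = names_all, chain_id = chain_id,
         resno_start = resno_start, lig_elements = lig_elements)
  }

  finish <- function(h, pdb_id) {
    .build_record(pdb_id, h$chain_id, h$resnames, h$ca, h$cb, h$resno_start,
                  h$lig_elements, h$lig_xyz)
  }

  if (relation == "positive") {
    pocket_names <- sample(.pocket_name_pool$positive, k, replace = TRUE)
    lig_el <- rep(c("C", "N", "O"), length.out = m)
    hA <- build_half("A", 1, pocket_names, lig_el)
    # transplant: rigid motion of A's pocket segment (+ noise), regrow B
    R <- .random_rotation()
    t0 <- stats::rnorm(3, sd = 20)
    seg <- hA$ca[seq_len(k), , drop = FALSE] %*% t(R) +
      matrix(t0, k, 3, byrow = TRUE)
    seg_dir <- hA$cb_dir[seq_len(k), , drop = FALSE] %*% t(R)
    attr(seg, "cb_dir") <- seg_dir
    hB <- build_half("B", 201, pocket_names, lig_el, fixed_pocket = seg)
    if (coordinate_noise > 0) {
      # perturb the transplanted micro-environment only after the decoy
      # chain is complete, so chain growth stays feasible at any noise level
      jitter <- function(x) x + matrix(stats::rnorm(length(x),
                                                    sd = coordinate_noise),
                                       nrow(x), 3)
      hB$ca[seq_len(k), ] <- jitter(hB$ca[seq_len(k), , drop = FALSE])
      hB$cb[seq_len(k), ] <- jitter(hB$cb[seq_len(k), , drop = FALSE])
      hB$lig_xyz <- jitter(hB$lig_xyz)
    }
    recA <- finish(hA, "SYNA")
    recB <- finish(hB, "SYNB")
    mapping <- pocket_alignment(data.frame(
      chainA = "A", resA = seq_len(k), icodeA = "",
      chainB = "B", resB = 200L + seq_len(k), icodeB = "",
      stringsAsFactors = FALSE), method = "reference")
    eq <- identity_equivalence(m)
  } else {
    # restrict each side's whole chain to its group alphabet so the two
    # contact profiles carry provably disjoint residue groups
    hA <- build_half("A", 1,
                     sample(.pocket_name_pool$negativeA, k, replace = TRUE),
                     rep("C", m), other_pool = .pocket_name_pool$negativeA)
    hB <- build_half("B", 201,
                     sample(.pocket_name_pool$negativeB, k, replace = TRUE),
                     rep(c("N", "O"), length.out = m),
                     other_pool = .pocket_name_pool$negativeB)
    recA <- finish(hA, "SYNA")
    recB <- finish(hB, "SYNB")
    mapping <- NULL
    eq <- identity_equivalence(m)
  }

  truth_contacts <- function(rec) {
    # independent (loop-based) contact enumeration
    out <- list()
    lig <- rec$ligand$atoms
    for (i in seq_len(nrow(lig))) {
      for (key in unique(.residue_key(rec$chain_atoms$chain,
                                      rec$chain_atoms$resno,
                                      rec$chain_atoms$icode))) {
        rows <- rec$chain_atoms[.residue_key(rec$chain_atoms$chain,
                                             rec$chain_atoms$resno,
                                             rec$chain_atoms$icode) == key, ]
        dmin <- Inf
        for (j in seq_len(nrow(rows))) {
          d <- sqrt((lig$x[i] - rows$x[j])^2 + (lig$y[i] - rows$y[j])^2 +
                      (lig$z[i] - rows$z[j])^2)
          if (d < dmin) dmin <- d
        }
        if (dmin <= 4.5 && !is.na(residue_group(rows$resname[1]))) {
          out[[length(out) + 1]] <- data.frame(
            ligand_atom = i, residue = key,
            group = residue_group(rows$resname[1]), distance = dmin,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  }

  list(recA = recA, recB = recB, mapping = mapping, eq = eq,
       relation = relation, noise = coordinate_noise,
       truth = list(contactsA = truth_contacts(recA),
                    contactsB = truth_contacts(recB)))
}

#' Generate a pocket alignment with controlled sequence order
#'
#' Mixes a sorted and a shuffled correspondence so that the ordinal
#' association of the produced alignment tracks `order_level`: +1 gives a
#' strictly sequential alignment (tau exactly 1), -1 a fully reversed one
#' (tau exactly -1), 0 a random order (tau 0 in expectation).
#' Intermediate levels interpolate; the exact realised tau is computed by
#' direct pair enumeration and returned as ground truth.
#'
#' @param nA,nB pocket sizes (sequence position ranges).
#' @param n_pairs alignment length (>= 2, <= min(nA, nB)).
#' @param order_level target ordinal association in `[-1, 1]`.
#' @param seed integer seed.
#' @return list with `posA`, `posB` (sequence positions), and `tau`
#'   (realised Kendall tau from exhaustive pair counting).
#' @export
make_alignment <- function(nA, nB, n_pairs, order_level, seed) {
  if (n_pairs < 2) .stopf("n_pairs must be >= 2, got %d", n_pairs)
  if (n_pairs > min(nA, nB)) .stopf("n_pairs exceeds min(nA, nB)")
  if (abs(order_level) > 1) .stopf("order_level outside [-1, 1]")
  set.seed(seed)
  posA <- sort(sample.int(nA, n_pairs))
  base <- sort(sample.int(nB, n_pairs))
  w <- abs(order_level)
  key <- w * seq_len(n_pairs) / n_pairs + (1 - w) * stats::runif(n_pairs)
  perm <- order(key)
  if (order_level < 0) perm <- rev(perm)
  posB <- base[order(perm)]
  # realised tau by direct enumeration over all C(n,2) pairs
  nc <- 0L
  nd <- 0L
  for (i in seq_len(n_pairs - 1)) {
    for (j in seq(i + 1, n_pairs)) {
      s <- (posA[j] - posA[i]) * (posB[j] - posB[i])
      if (s > 0) nc <- nc + 1L else if (s < 0) nd <- nd + 1L
    }
  }
  list(posA = posA, posB = posB,
       tau = (nc - nd) / (n_pairs * (n_pairs - 1) / 2))
}

#' Generate per-target screening scores with planted rank correlation
#'
#' Draws compound scores from a Gaussian copula: designated target pairs
#' (1,2), (3,4), ... share a latent correlation calibrated so their
#' Spearman rho equals `planted_rho` in expectation (Pearson
#' `2 sin(pi rho / 6)` under bivariate normality), and every target loads
#' on a synthetic molecular-weight covariate with Spearman coupling
#' `weight_coupling` (heavier compounds score more negative, emulating
#' the weight bias of docking scoring functions).  Scores are predicted
#' binding affinities: lower is better.
#'
#' @param n_compounds library size.
#' @param n_targets number of target pockets.
#' @param planted_rho Spearman correlation planted within target pairs.
#' @param weight_coupling Spearman correlation of every target's ranking
#'   with compound weight.
#' @param seed integer seed.
#' @return list with `scores` (n_compounds x n_targets matrix),
#'   `compound_ids`, `weight` (covariate), `paired_targets` (two-column
#'   matrix of planted pairs), and `planted` (rho, weight_coupling).
#' @export
make_rank_matrix <- function(n_compounds, n_targets, planted_rho = 0.7,
                             weight_coupling = 0.5, seed = 1) {
  if (abs(planted_rho) > 1) .stopf("planted_rho outside [-1, 1]")
  set.seed(seed)
  lambda <- 2 * sin(pi * weight_coupling / 6)
  r_target <- 2 * sin(pi * planted_rho / 6)
  r_e <- if (abs(1 - lambda^2) < 1e-12) 0 else
    (r_target - lambda^2) / (1 - lambda^2)
  if (abs(r_e) > 1 + 1e-12) {
    .stopf("infeasible correlation structure (latent correlation %.3f)", r_e)
  }
  r_e <- max(-1, min(1, r_e))
  W <- stats::rnorm(n_compounds)
  E <- matrix(stats::rnorm(n_compounds * n_targets), n_compounds, n_targets)
  pairs <- if (n_targets >= 2)
    cbind(seq(1, n_targets - 1, by = 2), seq(2, n_targets, by = 2)) else
    matrix(integer(0), 0, 2)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    E[, j] <- r_e * E[, i] + sqrt(1 - r_e^2) * E[, j]
  }
  latent <- lambda * W + sqrt(1 - lambda^2) * E
  scores <- -6 - 1.5 * latent      # affinity-like: lower = better
  colnames(scores) <- sprintf("target_%02d", seq_len(n_targets))
  list(scores = scores,
       compound_ids = sprintf("CPD%05d", seq_len(n_compounds)),
       weight = 300 + 80 * W,
       paired_targets = pairs,
       planted = list(rho = planted_rho, weight_coupling = weight_coupling))
}

#' Random toy molecule graph
#'
#' A random tree over a small element alphabet, optionally with one extra
#' ring-closing bond: enough structure to exercise fingerprinting,
#' Tanimoto similarity and common-substructure search, with no claim to
#' chemical realism.
#'
#' @param seed integer seed.
#' @param n_atoms atom count.
#' @param elements element alphabet to sample from.
#' @param ring add one ring-closing bond when possible.
#' @return a `molecule_graph`.
#' @export
make_toy_molecule <- function(seed, n_atoms = 8,
                              elements = c("C", "N", "O", "P", "S"),
                              ring = FALSE) {
  set.seed(seed)
  el <- sample(elements, n_atoms, replace = TRUE)
  bonds <- if (n_atoms > 1)
    cbind(2:n_atoms, vapply(2:n_atoms, function(i) sample.int(i - 1, 1), 0L)) else
    matrix(integer(0), 0, 2)
  if (ring && n_atoms >= 4) {
    extra <- sort(sample.int(n_atoms, 2))
    bonds <- rbind(bonds, extra)
  }
  molecule_graph(el, bonds)
}

#' Adenine nucleotide graphs (ADP / ATP)
#'
#' Hand-assembled heavy-atom connectivity of adenosine di- and
#' tri-phosphate (27 and 31 heavy atoms): the canonical worked example
#' for common-substructure atom equivalence, since the ADP graph is a
#' subgraph of ATP.
#'
#' @param which `"ADP"` or `"ATP"`.
#' @return a `molecule_graph`.
#' @export
make_nucleotide_graph <- function(which = c("ADP", "ATP")) {
  which <- match.arg(which)
  atoms <- c(
    # adenine
    N1 = "N", C2 = "C", N3 = "N", C4 = "C", C5 = "C", C6 = "C", N6 = "N",
    N7 = "N", C8 = "C", N9 = "N",
    # ribose
    C1s = "C", C2s = "C", O2s = "O", C3s = "C", O3s = "O", C4s = "C",
    O4s = "O", C5s = "C", O5s = "O",
    # alpha and beta phosphates
    PA = "P", O1A = "O", O2A = "O", O3A = "O",
    PB = "P", O1B = "O", O2B = "O", O3B = "O"
  )
  bonds <- rbind(
    c("N1", "C2"), c("C2", "N3"), c("N3", "C4"), c("C4", "C5"),
    c("C5", "C6"), c("C6", "N1"), c("C6", "N6"), c("C5", "N7"),
    c("N7", "C8"), c("C8", "N9"), c("N9", "C4"),
    c("N9", "C1s"), c("C1s", "C2s"), c("C2s", "O2s"), c("C2s", "C3s"),
    c("C3s", "O3s"), c("C3s", "C4s"), c("C4s", "O4s"), c("O4s", "C1s"),
    c("C4s", "C5s"), c("C5s", "O5s"),
    c("O5s", "PA"), c("PA", "O1A"), c("PA", "O2A"), c("PA", "O3A"),
    c("O3A", "PB"), c("PB", "O1B"), c("PB", "O2B"), c("PB", "O3B")
  )
  if (which == "ATP") {
    atoms <- c(atoms, PG = "P", O1G = "O", O2G = "O", O3G = "O")
    bonds <- rbind(bonds, c("O3B", "PG"), c("PG", "O1G"), c("PG", "O2G"),
                   c("PG", "O3G"))
  }
  idx <- stats::setNames(seq_along(atoms), names(atoms))
  molecule_graph(unname(atoms),
                 cbind(idx[bonds[, 1]], idx[bonds[, 2]]))
}
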