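# Independent brute-force oracles.  These deliberately re-derive each
# quantity by the most naive route available (enumeration, grid search,
# explicit loops) and must stay independent of the package code paths
# they check.

# all permutations of a vector (n <= ~7)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(perms(v[-i]), function(p) c(v[i], p))
  }))
}

# exhaustive minimum-cost assignment
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  min(vapply(perms(seq_len(n)), function(p)
    sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# Kendall tau by explicit double loop
brute_tau <- function(posA, posB) {
  n <- length(posA)
  nc <- 0
  nd <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- (posA[j] - posA[i]) * (posB[j] - posB[i])
      if (s > 0) nc <- nc + 1 else if (s < 0) nd <- nd + 1
    }
  }
  list(nc = nc, nd = nd, tau = (nc - nd) / (n * (n - 1) / 2))
}

# minimum RMSD over rigid motions by random-restart orientation search
# (rotation parameterised by axis-angle; translation optimal in closed
# form once centred)
brute_min_rmsd <- function(A, B, n_starts = 60) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  rot <- function(p) {
    theta <- sqrt(sum(p^2))
    if (theta < 1e-12) return(diag(3))
    k <- p / theta
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  }
  obj <- function(p) sqrt(mean(rowSums((Bc %*% t(rot(p)) - Ac)^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- stats::runif(3, -pi, pi)
    o <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# exhaustive maximum connected common substructure for tiny graphs:
# enumerate every injective mapping between vertex subsets, check element
# labels and connectivity of the shared-bond subgraph
brute_mcs_size <- function(molA, molB) {
  nA <- length(molA$elements)
  nB <- length(molB$elements)
  adjm <- function(mol) {
    n <- length(mol$elements)
    m <- matrix(FALSE, n, n)
    if (nrow(mol$bonds) > 0) {
      m[mol$bonds] <- TRUE
      m[mol$bonds[, c(2, 1), drop = FALSE]] <- TRUE
    }
    m
  }
  mA <- adjm(molA)
  mB <- adjm(molB)
  connected_common <- function(sub, img) {
    k <- length(sub)
    if (k == 1) return(TRUE)
    shared <- matrix(FALSE, k, k)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        shared[i, j] <- shared[j, i] <-
          mA[sub[i], sub[j]] && mB[img[i], img[j]]
      }
    }
    seen <- rep(FALSE, k)
    stack <- 1
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(shared[v, ] & !seen))
    }
    all(seen)
  }
  best <- 0
  for (k in seq(min(nA, nB), 1)) {
    if (k <= best) break
    subs <- utils::combn(nA, k, simplify = FALSE)
    imgs <- utils::combn(nB, k, simplify = FALSE)
    for (sub in subs) {
      for (img_set in imgs) {
        for (img in perms(img_set)) {
          if (!all(molA$elements[sub] == molB$elements[img])) next
          if (connected_common(sub, img)) {
            best <- max(best, k)
            break
          }
        }
        if (best >= k) break
      }
      if (best >= k) break
    }
  }
  best
}

# naive all-pairs contact enumeration on a complex record
brute_contacts <- function(record, cutoff = 4.5) {
  lig <- record$ligand$atoms
  ca <- record$chain_atoms
  out <- list()
  for (i in seq_len(nrow(lig))) {
    keys <- unique(paste(ca$chain, ca$resno, ca$icode, sep = "|"))
    for (key in keys) {
      rows <- ca[paste(ca$chain, ca$resno, ca$icode, sep = "|") == key, ]
      dmin <- Inf
      for (j in seq_len(nrow(rows))) {
        d <- sqrt((lig$x[i] - rows$x[j])^2 + (lig$y[i] - rows$y[j])^2 +
                    (lig$z[i] - rows$z[j])^2)
        dmin <- min(dmin, d)
      }
      if (dmin <= cutoff && !is.na(residue_group(rows$resname[1]))) {
        out[[length(out) + 1]] <- data.frame(
          ligand_atom = i, key = key, distance = dmin)
      }
    }
  }
  if (length(out) == 0) {
    data.frame(ligand_atom = integer(0), key = character(0),
               distance = numeric(0))
  } else {
    do.call(rbind, out)
  }
}

# a minimal hand-formatted PDB ATOM/HETATM line, independent of the
# package's writer
pdb_line <- function(type, serial, name, resname, chain, resno, x, y, z,
                     occ = 1, altloc = " ", icode = " ", element = "") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial,
          if (nchar(element) == 1) paste0(" ", name) else name,
          altloc, resname, chain, resno, icode, x, y, z, occ, 0, element)
}

# tiny fake complex record for curation-stage tests that only touch the
# ligand, residue count and site centroid
toy_record <- function(id, n_res = 60, lig_elements = c("C", "C", "C", "C", "C", "C"),
                       centre = c(0, 0, 0), pdb_id = id, chain_id = "A") {
  m <- length(lig_elements)
  xyz <- cbind(centre[1] + 1.5 * (seq_len(m) - (m + 1) / 2),
               centre[2], centre[3])
  lig <- data.frame(serial = seq_len(m), name = paste0(lig_elements, seq_len(m)),
                    element = lig_elements, x = xyz[, 1], y = xyz[, 2],
                    z = xyz[, 3], occupancy = 1, altloc = "",
                    chain = chain_id, resno = 500L, icode = "",
                    resname = "LIG", is_hetero = TRUE,
                    stringsAsFactors = FALSE)
  res <- data.frame(chain = chain_id, resno = seq_len(n_res), icode = "",
                    resname = "ALA", stringsAsFactors = FALSE)
  structure(list(id = id, pdb_id = pdb_id, chain_id = chain_id,
                 residues = res, sequence = strrep("A", n_res),
                 ligand = list(res_name = "LIG", atoms = lig,
                               parent_chain = chain_id),
                 binding_residues = res[seq_len(min(8, n_res)), ],
                 contacts = data.frame(), pocket_source = "ligand-derived"),
            class = "complex_record")
}
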