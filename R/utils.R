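#' Minimum-cost one-to-one assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a square cost matrix by the
#' O(n^3) shortest-augmenting-path formulation with row/column potentials.
#' Used internally to pair binding residues by inter-atomic distance after
#' ligand superposition; exported because minimum-cost matching is handy
#' when post-processing external pocket alignments as well.
#'
#' @param cost numeric matrix of assignment costs; rectangular matrices are
#'   padded internally with zero-cost dummy rows/columns.
#' @return integer vector `a` of length `nrow(cost)`: `a[i]` is the column
#'   assigned to row `i`, or `NA` for rows matched to a dummy column.
#' @examples
#' solve_assignment(matrix(c(4, 2, 1, 3), 2, 2))
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || !is.numeric(cost)) stop("cost must be a numeric matrix")
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  nr <- nrow(cost)
  nc <- ncol(cost)
  n <- max(nr, nc)
  m <- matrix(0, n, n)
  m[seq_len(nr), seq_len(nc)] <- cost

  # potentials u (rows), v (cols); p[j+1] = row currently matched to col j
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- m[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    if (p[j + 1] > 0 && p[j + 1] <= nr && j <= nc) ans[p[j + 1]] <- j
  }
  ans
}

# pairwise Euclidean distances between the rows of two n x 3 matrices
.cross_dist <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# midranks: rank 1 = smallest value (best affinity when scores are
# predicted binding energies)
.midrank <- function(x) rank(x, ties.method = "average")

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.msgf <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))

#' Write a data frame as tab-separated text
#'
#' Plain TSV writer used for all on-disk tables (contacts, alignments,
#' manifests, reports): no quoting, no row names.
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}
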