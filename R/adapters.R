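# Parsers for the outputs of external pocket-matching tools, docking
# score tables and pocket predictors.  Third-party output dialects drift
# between versions, so each parser documents the exact grammar it accepts
# and is developed against fixture texts of that grammar; the raw text is
# retained on the result for audit.
#
# Alignment report grammar (all three aligner dialects):
#   - a score line:   apoc:        "PS-score = <x>  P-value = <p>"
#                     siteengine:  "Match score: <x>"
#                     glosa:       "GA-score = <x>"
#   - an alignment block opened by a line starting with ">Alignment",
#     then one row per residue pair:
#       <idx>  <chainA> <resA><icodeA?> <resnameA>  <chainB> <resB><icodeB?> <resnameB>
#     (whitespace-separated; insertion codes written as a trailing letter
#     on the residue number, e.g. "100A").  Row order is preserved -- it
#     is the input to the Kendall tau statistic.

.parse_resfield <- function(x, line_no, line) {
  m <- regmatches(x, regexec("^(-?[0-9]+)([A-Za-z]?)$", x))[[1]]
  if (length(m) != 3) {
    .stopf("malformed residue field '%s' at line %d: %s", x, line_no, line)
  }
  list(resno = as.integer(m[2]), icode = m[3])
}

#' Parse an external pocket-aligner report
#'
#' @param tool one of `"apoc"`, `"siteengine"`, `"glosa"`.
#' @param text report text (single string or lines).
#' @return list with `alignment` (a `pocket_alignment`, method = tool),
#'   `score` (a `method_score`), and `raw` (the input lines).
#' @export
parse_alignment_report <- function(tool = c("apoc", "siteengine", "glosa"),
                                   text) {
  tool <- match.arg(tool)
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text

  score <- NA_real_
  pval <- NA_real_
  pat <- switch(tool,
                apoc = "PS-score\\s*=\\s*([0-9.eE+-]+)",
                siteengine = "Match score\\s*:\\s*([0-9.eE+-]+)",
                glosa = "GA-score\\s*=\\s*([0-9.eE+-]+)")
  hit <- regmatches(lines, regexec(pat, lines))
  for (h in hit) if (length(h) == 2) score <- as.numeric(h[2])
  ph <- regmatches(lines, regexec("P-value\\s*=\\s*([0-9.eE+-]+)", lines))
  for (h in ph) if (length(h) == 2) pval <- as.numeric(h[2])
  if (is.na(score)) warning(sprintf("no %s score found in report", tool))

  start <- grep("^>Alignment", lines)
  rows <- list()
  if (length(start) > 0) {
    i <- start[1] + 1
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln) || grepl("^[>#]", ln)) break
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) != 7) {
        .stopf("malformed alignment row at line %d: %s", i, lines[i])
      }
      ra <- .parse_resfield(f[3], i, lines[i])
      rb <- .parse_resfield(f[6], i, lines[i])
      rows[[length(rows) + 1]] <- data.frame(
        chainA = f[2], resA = ra$resno, icodeA = ra$icode,
        chainB = f[5], resB = rb$resno, icodeB = rb$icode,
        stringsAsFactors = FALSE)
      i <- i + 1
    }
  }
  pairs <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chainA = character(0), resA = integer(0), icodeA = character(0),
               chainB = character(0), resB = integer(0), icodeB = character(0))
  if (nrow(pairs) == 0) warning("empty alignment block")
  list(alignment = pocket_alignment(pairs, method = tool, score = score,
                                    empty = nrow(pairs) == 0),
       score = method_score(tool, score, pval),
       raw = lines)
}

#' Parse a per-target docking score table
#'
#' Accepts whitespace- or tab-separated rows `compound_id  score`
#' (comment lines starting with `#` and an optional header row are
#' skipped).  Scores are predicted binding affinities: the most negative
#' score receives rank 1; ties receive midranks.
#'
#' @param tool tool tag recorded on the result (`"vina"`, `"rdock"`, ...).
#' @param text score table text.
#' @param target_id target identifier.
#' @return a `rank_vector`.
#' @export
parse_screening_scores <- function(tool, text, target_id = tool) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) > 0 &&
      is.na(suppressWarnings(as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]][2])))) {
    lines <- lines[-1]   # header row
  }
  ids <- character(0)
  vals <- numeric(0)
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 2) .stopf("malformed score row: %s", lines[i])
    v <- suppressWarnings(as.numeric(f[2]))
    if (is.na(v)) .stopf("non-numeric score '%s' for compound %s", f[2], f[1])
    ids <- c(ids, f[1])
    vals <- c(vals, v)
  }
  if (anyDuplicated(ids)) {
    .stopf("duplicate compound id: %s", ids[duplicated(ids)][1])
  }
  names(vals) <- ids
  rank_vector(target_id, vals)
}

#' Parse a pocket-predictor report
#'
#' Accepts blocks opened by `Pocket <rank>:` followed by residue lines
#' `<chain> <resno><icode?>`, one per residue.  Pocket ranks are
#' preserved (rank 1 = top pocket).  When `structure_residues` is given,
#' predicted residues absent from the structure are dropped with a
#' warning.
#'
#' @param tool tool tag (`"fpocket"`, ...).
#' @param text predictor output text.
#' @param structure_residues optional character vector of valid residue
#'   keys `"chain|resno|icode"`.
#' @return list of pockets, each a list with `rank` and `residues`
#'   (character vector of residue keys); empty list when no pockets.
#' @export
parse_pocket_prediction <- function(tool, text, structure_residues = NULL) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  heads <- grep("^\\s*Pocket\\s+[0-9]+\\s*:", lines)
  if (length(heads) == 0) return(list())
  bounds <- c(heads, length(lines) + 1)
  pockets <- list()
  for (k in seq_along(heads)) {
    rank <- as.integer(sub("^\\s*Pocket\\s+([0-9]+)\\s*:.*$", "\\1",
                           lines[heads[k]]))
    body <- lines[seq(heads[k] + 1, bounds[k + 1] - 1)]
    body <- trimws(body[nzchar(trimws(body))])
    keys <- character(0)
    for (i in seq_along(body)) {
      f <- strsplit(body[i], "\\s+")[[1]]
      if (length(f) != 2) .stopf("malformed pocket residue line: %s", body[i])
      r <- .parse_resfield(f[2], heads[k] + i, body[i])
      keys <- c(keys, .residue_key(f[1], r$resno, r$icode))
    }
    if (!is.null(structure_residues)) {
      missing <- setdiff(keys, structure_residues)
      if (length(missing) > 0) {
        warning(sprintf("pocket %d: dropped %d residue(s) absent from the structure",
                        rank, length(missing)))
        keys <- intersect(keys, structure_residues)
      }
    }
    pockets[[k]] <- list(rank = rank, residues = keys)
  }
  pockets[order(vapply(pockets, function(p) p$rank, numeric(1)))]
}

#' Rank predicted pockets against a truth residue set
#'
#' Scores every predicted pocket by MCC against the contact-derived
#' binding residues and reports which predictor rank matches best --
#' useful to audit whether a predictor's top pocket is the ligand-bound
#' one.
#'
#' @param pockets list from [parse_pocket_prediction()].
#' @param truth_residues character vector of true binding-residue keys.
#' @param all_residues character vector of all chain residue keys.
#' @return data frame: rank, n_residues, mcc; ordered by predictor rank.
#' @export
score_predicted_pockets <- function(pockets, truth_residues, all_residues) {
  rows <- lapply(pockets, function(p) {
    pred <- intersect(p$residues, all_residues)
    tp <- length(intersect(pred, truth_residues))
    fp <- length(setdiff(pred, truth_residues))
    fn <- length(setdiff(truth_residues, pred))
    tn <- length(all_residues) - tp - fp - fn
    data.frame(rank = p$rank, n_residues = length(pred),
               mcc = binary_mcc(tp, fp, tn, fn))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(rank = integer(0), n_residues = integer(0),
                               mcc = numeric(0)) else out
}
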