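# Compilation of a benchmark of Positive/Negative pocket pairs from a set
# of complex records, as a chain of verifiable stages:
#   1. filter_complexes      length / single-ligand / drug-likeness
#   2. cluster_sequences     greedy clustering at 40% global identity
#   3. select_representatives  within-cluster dedup by ligand TC and
#                              binding-site separation
#   4. pocket_quality_filter   predicted-pocket MCC >= 0.4
#   5. leader_cluster (chem)   ligand clusters at TC 0.7
#   6. enumerate_pairs         TM-score < 0.4 pairs within (Positive) and
#                              between (Negative) ligand clusters
# Every rejection is logged with the rule that fired, and
# verify_manifest() re-audits the final product.

#' Curation configuration
#'
#' Defaults: chains of 50-999 residues, drug-likeness at Tanimoto >= 0.5
#' to at least one library drug, sequence clustering at 40% identity,
#' within-cluster ligand dissimilarity threshold TC < 0.5 or binding-site
#' separation >= 8 A, predicted-pocket MCC >= 0.4, ligand clustering at
#' TC 0.7, and global dissimilarity at TM-score < 0.4.
#'
#' @param min_len,max_len chain length bounds (residues).
#' @param drug_tc minimum Tanimoto to a library drug.
#' @param seq_cluster sequence identity threshold for clustering.
#' @param multi_ligand_tc within-cluster ligand TC threshold.
#' @param site_separation within-cluster site-centroid separation (A).
#' @param pocket_mcc minimum MCC of a predicted pocket vs the
#'   contact-derived truth.
#' @param ligand_cluster_tc Tanimoto threshold for ligand clustering.
#' @param tm_max maximum TM-score for a pair to count as globally
#'   dissimilar.
#' @param representative_rule `"or"` (default): within a sequence cluster
#'   a record is kept when its ligand is dissimilar (TC below
#'   `multi_ligand_tc`) *or* its site is distant (`>= site_separation`);
#'   `"and"` requires both.
#' @return a list of class `curation_config`.
#' @export
curation_config <- function(min_len = 50, max_len = 999, drug_tc = 0.5,
                            seq_cluster = 0.40, multi_ligand_tc = 0.5,
                            site_separation = 8.0, pocket_mcc = 0.4,
                            ligand_cluster_tc = 0.7, tm_max = 0.4,
                            representative_rule = c("or", "and")) {
  structure(list(min_len = min_len, max_len = max_len, drug_tc = drug_tc,
                 seq_cluster = seq_cluster, multi_ligand_tc = multi_ligand_tc,
                 site_separation = site_separation, pocket_mcc = pocket_mcc,
                 ligand_cluster_tc = ligand_cluster_tc, tm_max = tm_max,
                 representative_rule = match.arg(representative_rule)),
            class = "curation_config")
}

.log_row <- function(id, stage, decision, rule = "") {
  data.frame(id = id, stage = stage, decision = decision, rule = rule,
             stringsAsFactors = FALSE)
}

.record_fp <- function(record) {
  path_fingerprint(perceive_molecule(record$ligand))
}

.site_centroid <- function(record) {
  colMeans(record$ligand$atoms[, c("x", "y", "z")])
}

#' Stage 1: length, single-ligand and drug-likeness filters
#'
#' Keeps records whose chain length lies in `[min_len, max_len]`, whose
#' chain carries exactly one qualifying ligand among the input records,
#' and whose ligand has Tanimoto similarity at or above `drug_tc` to at
#' least one fingerprint in the drug library.
#'
#' @param records list of `complex_record` objects.
#' @param drugs list of drug fingerprints (from [path_fingerprint()]).
#' @param cfg a `curation_config`.
#' @return list with `records` (survivors) and `log` (decision table).
#' @export
filter_complexes <- function(records, drugs, cfg = curation_config()) {
  if (length(drugs) == 0) .stopf("drug fingerprint library is empty")
  if (length(records) == 0) {
    warning("no input records")
    return(list(records = list(),
                log = data.frame(id = character(0), stage = character(0),
                                 decision = character(0), rule = character(0))))
  }
  logs <- list()
  keep <- list()
  chain_of <- vapply(records, function(r) paste(r$pdb_id, r$chain_id), "")
  multi <- names(table(chain_of))[table(chain_of) > 1]
  for (r in records) {
    n <- nrow(r$residues)
    if (n < cfg$min_len || n > cfg$max_len) {
      logs[[r$id]] <- .log_row(r$id, "filter_complexes", "reject", "length")
      next
    }
    if (paste(r$pdb_id, r$chain_id) %in% multi) {
      logs[[r$id]] <- .log_row(r$id, "filter_complexes", "reject", "multi_ligand")
      next
    }
    fp <- .record_fp(r)
    tc <- vapply(drugs, tanimoto, numeric(1), b = fp)
    if (max(tc) < cfg$drug_tc) {
      logs[[r$id]] <- .log_row(r$id, "filter_complexes", "reject", "drug_tc")
      next
    }
    logs[[r$id]] <- .log_row(r$id, "filter_complexes", "keep")
    keep[[r$id]] <- r
  }
  list(records = keep, log = do.call(rbind, logs))
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) via
#' Biostrings; identity is exact matches over the alignment length
#' (including gap columns).
#'
#' @param seq1,seq2 one-letter amino-acid strings.
#' @param gap_opening,gap_extension affine gap parameters.
#' @return identity fraction in `[0, 1]`.
#' @export
sequence_identity <- function(seq1, seq2, gap_opening = 10, gap_extension = 0.5) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::pattern(aln)))
}

#' Stage 2: greedy sequence clustering
#'
#' Longest-first greedy clustering: each sequence joins the first cluster
#' whose representative it matches at `identity_threshold` or better,
#' otherwise founds a new cluster.  Deterministic.
#'
#' @param records list of `complex_record` objects.
#' @param identity_threshold global identity threshold (0.40 by default).
#' @return integer cluster assignment named by record id.
#' @export
cluster_sequences <- function(records, identity_threshold = 0.40) {
  n <- length(records)
  if (n == 0) return(integer(0))
  seqs <- vapply(records, function(r) r$sequence, "")
  ids <- vapply(records, function(r) r$id, "")
  ord <- order(-nchar(seqs), seq_len(n))
  assignment <- integer(n)
  reps <- integer(0)
  for (i in ord) {
    joined <- FALSE
    for (ci in seq_along(reps)) {
      if (sequence_identity(seqs[i], seqs[reps[ci]]) >= identity_threshold) {
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
  names(assignment) <- ids
  assignment
}

#' Stage 3: representative selection within a sequence cluster
#'
#' Retains, largest-chain-first, a maximal subset of records that are
#' mutually non-redundant: a candidate is kept when, against every record
#' already kept, its ligand is chemically dissimilar (TC below
#' `multi_ligand_tc`) or its binding site is distant (ligand-centroid
#' separation at or above `site_separation`); with
#' `representative_rule = "and"` both must hold.
#'
#' @param cluster list of `complex_record` objects in one sequence cluster.
#' @param cfg a `curation_config`.
#' @return list with `records` (kept) and `log`.
#' @export
select_representatives <- function(cluster, cfg = curation_config()) {
  if (length(cluster) <= 1) {
    ids <- vapply(cluster, function(r) r$id, "")
    return(list(records = cluster,
                log = if (length(ids)) .log_row(ids, "select_representatives", "keep")
                      else NULL))
  }
  fps <- lapply(cluster, .record_fp)
  cents <- lapply(cluster, .site_centroid)
  sizes <- vapply(cluster, function(r) nrow(r$residues), numeric(1))
  ord <- order(-sizes, seq_along(cluster))
  kept <- integer(0)
  logs <- list()
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      tc_dissimilar <- tanimoto(fps[[i]], fps[[j]]) < cfg$multi_ligand_tc
      far <- sqrt(sum((cents[[i]] - cents[[j]])^2)) >= cfg$site_separation
      distinct <- if (cfg$representative_rule == "or") tc_dissimilar || far
                  else tc_dissimilar && far
      if (!distinct) {
        ok <- FALSE
        break
      }
    }
    id <- cluster[[i]]$id
    if (ok) {
      kept <- c(kept, i)
      logs[[id]] <- .log_row(id, "select_representatives", "keep")
    } else {
      logs[[id]] <- .log_row(id, "select_representatives", "reject", "redundant_site")
    }
  }
  list(records = cluster[sort(kept)], log = do.call(rbind, logs))
}

#' Stage 4: predicted-pocket quality filter
#'
#' For each record, the predicted pocket (a set of residue keys from an
#' external pocket predictor, or a ligand-derived surrogate) is scored by
#' MCC over all chain residues against the contact-derived binding
#' residues; records below `pocket_mcc` or without a prediction are
#' dropped.
#'
#' @param records list of `complex_record` objects.
#' @param predicted_pockets named list (by record id) of character vectors
#'   of residue keys `"chain|resno|icode"`.
#' @param cfg a `curation_config`.
#' @return list with `records`, `log`, and `mcc` (named numeric).
#' @export
pocket_quality_filter <- function(records, predicted_pockets,
                                  cfg = curation_config()) {
  keep <- list()
  logs <- list()
  mccs <- numeric(0)
  for (r in records) {
    pred <- predicted_pockets[[r$id]]
    if (is.null(pred)) {
      logs[[r$id]] <- .log_row(r$id, "pocket_quality_filter", "reject",
                               "missing_prediction")
      next
    }
    allres <- .residue_key(r$residues$chain, r$residues$resno, r$residues$icode)
    truth <- .residue_key(r$binding_residues$chain, r$binding_residues$resno,
                          r$binding_residues$icode)
    pred <- intersect(pred, allres)
    tp <- length(intersect(pred, truth))
    fp <- length(setdiff(pred, truth))
    fn <- length(setdiff(truth, pred))
    tn <- length(allres) - tp - fp - fn
    mcc <- binary_mcc(tp, fp, tn, fn)
    mccs[r$id] <- mcc
    if (mcc >= cfg$pocket_mcc) {
      logs[[r$id]] <- .log_row(r$id, "pocket_quality_filter", "keep")
      keep[[r$id]] <- r
    } else {
      logs[[r$id]] <- .log_row(r$id, "pocket_quality_filter", "reject",
                               "pocket_mcc")
    }
  }
  list(records = keep, log = do.call(rbind, logs), mcc = mccs)
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "~")
}

#' TM-score lookup closure from a table
#'
#' @param tm_table data frame with columns idA, idB, tm_score (unordered
#'   pairs).
#' @return function `(idA, idB) -> tm_score or NA`.
#' @export
tm_lookup_from_table <- function(tm_table) {
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(tm_table))) {
    assign(.pair_key(tm_table$idA[i], tm_table$idB[i]), tm_table$tm_score[i],
           envir = env)
  }
  function(idA, idB) {
    k <- .pair_key(idA, idB)
    if (exists(k, envir = env, inherits = FALSE)) get(k, envir = env) else NA_real_
  }
}

#' Stage 6: Positive/Negative pair enumeration
#'
#' Positives are all record pairs within one ligand cluster whose
#' externally supplied TM-score is below `tm_max` (globally dissimilar
#' proteins binding similar chemistry).  Negatives are all pairs of
#' per-cluster representative records from *different* ligand clusters,
#' again at TM-score below `tm_max`.  Pairs without a TM-score are
#' skipped and counted.
#'
#' @param records list of `complex_record` objects.
#' @param ligand_clusters integer cluster assignment named by record id
#'   (e.g. from [leader_cluster()] on the ligands).
#' @param tm_lookup function `(idA, idB) -> tm_score` (see
#'   [tm_lookup_from_table()]).
#' @param cfg a `curation_config`.
#' @return list with data frames `positive_pairs`, `negative_pairs`
#'   (idA, idB, tm_score), `representatives` (per-cluster), and
#'   `n_skipped` (pairs without a TM-score).
#' @export
enumerate_pairs <- function(records, ligand_clusters, tm_lookup,
                            cfg = curation_config()) {
  ids <- vapply(records, function(r) r$id, "")
  cl <- ligand_clusters[ids]
  if (anyNA(cl)) .stopf("ligand cluster missing for some records")
  n_skipped <- 0L
  scan_pairs <- function(id_set) {
    rows <- list()
    if (length(id_set) >= 2) {
      cmb <- utils::combn(sort(id_set), 2)
      for (k in seq_len(ncol(cmb))) {
        tm <- tm_lookup(cmb[1, k], cmb[2, k])
        if (is.na(tm)) {
          n_skipped <<- n_skipped + 1L
          next
        }
        if (tm < cfg$tm_max) {
          rows[[k]] <- data.frame(idA = cmb[1, k], idB = cmb[2, k],
                                  tm_score = tm, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) data.frame(idA = character(0), idB = character(0),
                                 tm_score = numeric(0)) else out
  }
  positives <- do.call(rbind, lapply(split(ids, cl), scan_pairs))
  rownames(positives) <- NULL
  positives <- unique(positives)

  # representative of each ligand cluster: the record with the most
  # binding residues (ties -> first id alphabetically)
  nbind <- vapply(records, function(r) nrow(r$binding_residues), numeric(1))
  reps <- vapply(split(seq_along(ids), cl), function(ii) {
    ii <- ii[order(-nbind[ii], ids[ii])]
    ids[ii[1]]
  }, "")
  negatives <- scan_pairs(unname(reps))
  rownames(negatives) <- NULL
  list(positive_pairs = positives, negative_pairs = negatives,
       representatives = reps, n_skipped = n_skipped)
}

#' Run the full curation pipeline
#'
#' Chains all stages and returns a `dataset_manifest` with full
#' provenance: every input record appears either among the survivors or
#' in the filter log with the rule that rejected it.
#'
#' @param records list of `complex_record` objects.
#' @param drugs list of drug fingerprints.
#' @param tm_lookup TM-score lookup function.
#' @param predicted_pockets named list of predicted pocket residue-key
#'   sets; by default the contact-derived pockets themselves (surrogate
#'   for an external pocket predictor; every record then passes stage 4).
#' @param cfg a `curation_config`.
#' @return object of class `dataset_manifest`.
#' @export
curate_dataset <- function(records, drugs, tm_lookup,
                           predicted_pockets = NULL,
                           cfg = curation_config()) {
  s1 <- filter_complexes(records, drugs, cfg)
  logs <- list(s1$log)

  seq_cl <- cluster_sequences(s1$records, cfg$seq_cluster)
  s3_records <- list()
  for (ci in unique(seq_cl)) {
    members <- s1$records[names(seq_cl)[seq_cl == ci]]
    s3 <- select_representatives(members, cfg)
    logs <- c(logs, list(s3$log))
    s3_records <- c(s3_records, s3$records)
  }

  if (is.null(predicted_pockets)) {
    predicted_pockets <- lapply(s3_records, function(r)
      .residue_key(r$binding_residues$chain, r$binding_residues$resno,
                   r$binding_residues$icode))
    names(predicted_pockets) <- vapply(s3_records, function(r) r$id, "")
  }
  s4 <- pocket_quality_filter(s3_records, predicted_pockets, cfg)
  logs <- c(logs, list(s4$log))

  survivors <- s4$records
  mols <- lapply(survivors, function(r) perceive_molecule(r$ligand))
  lig_cl <- leader_cluster(mols, threshold = cfg$ligand_cluster_tc)$assignment
  names(lig_cl) <- vapply(survivors, function(r) r$id, "")

  pairs <- enumerate_pairs(survivors, lig_cl, tm_lookup, cfg)
  filter_log <- do.call(rbind, Filter(Negate(is.null), logs))
  rownames(filter_log) <- NULL
  structure(list(
    complexes = unname(vapply(survivors, function(r) r$id, "")),
    sequence_clusters = seq_cl,
    ligand_clusters = lig_cl,
    positive_pairs = pairs$positive_pairs,
    negative_pairs = pairs$negative_pairs,
    representatives = pairs$representatives,
    n_skipped_pairs = pairs$n_skipped,
    filter_log = filter_log,
    config = cfg
  ), class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf(
    "dataset_manifest: %d complexes, %d ligand clusters, %d positive / %d negative pairs\n",
    length(x$complexes), length(unique(x$ligand_clusters)),
    nrow(x$positive_pairs), nrow(x$negative_pairs)))
  invisible(x)
}

#' Audit a dataset manifest
#'
#' Re-checks every manifest invariant: TM-scores below the threshold on
#' all listed pairs, positive pairs share a ligand cluster while negative
#' pairs never do, no self pairs, no duplicated unordered pairs, and all
#' pair members among the curated complexes.
#'
#' @param manifest a `dataset_manifest`.
#' @param cfg configuration to audit against (defaults to the one stored
#'   on the manifest).
#' @return data frame of violations (zero rows iff compliant).
#' @export
verify_manifest <- function(manifest, cfg = manifest$config) {
  v <- list()
  add <- function(rule, detail) {
    v[[length(v) + 1]] <<- data.frame(rule = rule, detail = detail,
                                      stringsAsFactors = FALSE)
  }
  check_pairs <- function(df, set_name, same_cluster) {
    if (nrow(df) == 0) return(invisible())
    for (i in seq_len(nrow(df))) {
      a <- df$idA[i]; b <- df$idB[i]
      if (a == b) add("self_pair", sprintf("%s: %s", set_name, a))
      if (!is.na(df$tm_score[i]) && df$tm_score[i] >= cfg$tm_max) {
        add("tm_max", sprintf("%s: %s~%s tm=%.2f", set_name, a, b, df$tm_score[i]))
      }
      if (!all(c(a, b) %in% manifest$complexes)) {
        add("unknown_record", sprintf("%s: %s~%s", set_name, a, b))
      } else {
        shared <- manifest$ligand_clusters[a] == manifest$ligand_clusters[b]
        if (same_cluster && !shared) {
          add("cluster_membership", sprintf("positive pair across clusters: %s~%s", a, b))
        }
        if (!same_cluster && shared) {
          add("cluster_membership", sprintf("negative pair within a cluster: %s~%s", a, b))
        }
      }
    }
    keys <- .pair_key(df$idA, df$idB)
    if (anyDuplicated(keys)) {
      add("duplicate_pair", sprintf("%s: %s", set_name,
                                    paste(keys[duplicated(keys)], collapse = ",")))
    }
  }
  check_pairs(manifest$positive_pairs, "positive", TRUE)
  check_pairs(manifest$negative_pairs, "negative", FALSE)
  both <- intersect(.pair_key(manifest$positive_pairs$idA, manifest$positive_pairs$idB),
                    .pair_key(manifest$negative_pairs$idA, manifest$negative_pairs$idB))
  if (length(both) > 0) add("set_overlap", paste(both, collapse = ","))
  out <- do.call(rbind, v)
  if (is.null(out)) data.frame(rule = character(0), detail = character(0)) else out
}

#' Write a manifest to a directory
#'
#' Tables as TSV plus a YAML snapshot of the configuration.
#'
#' @param manifest a `dataset_manifest`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(data.frame(id = manifest$complexes,
                       sequence_cluster = manifest$sequence_clusters[manifest$complexes],
                       ligand_cluster = manifest$ligand_clusters[manifest$complexes]),
            file.path(dir, "complexes.tsv"))
  write_tsv(manifest$positive_pairs, file.path(dir, "positive_pairs.tsv"))
  write_tsv(manifest$negative_pairs, file.path(dir, "negative_pairs.tsv"))
  write_tsv(manifest$filter_log, file.path(dir, "filter_log.tsv"))
  yaml::write_yaml(unclass(manifest$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
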