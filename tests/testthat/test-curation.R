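fp_of <- function(rec) path_fingerprint(perceive_molecule(rec$ligand))

test_that("complex filtering enforces length, single-ligand and drug-likeness rules", {
  good <- toy_record("good", n_res = 60, lig_elements = rep("C", 6))
  long <- toy_record("long", n_res = 1000, lig_elements = rep("C", 6))
  alien <- toy_record("alien", n_res = 60,
                      lig_elements = c("N", "O", "N", "O", "N", "O"))
  twin1 <- toy_record("twin1", n_res = 60, pdb_id = "TWIN")
  twin2 <- toy_record("twin2", n_res = 60, pdb_id = "TWIN")
  drugs <- list(fp_of(good))   # library = the C6 chain itself

  out <- filter_complexes(list(good, long, alien, twin1, twin2), drugs)
  expect_equal(names(out$records), "good")
  lg <- out$log
  expect_equal(lg$rule[lg$id == "long"], "length")
  expect_equal(lg$rule[lg$id == "alien"], "drug_tc")
  expect_equal(lg$rule[lg$id == "twin1"], "multi_ligand")
  expect_equal(lg$rule[lg$id == "twin2"], "multi_ligand")
  # every input appears exactly once in the log
  expect_setequal(lg$id, c("good", "long", "alien", "twin1", "twin2"))

  expect_warning(filter_complexes(list(), drugs), "no input")
  expect_error(filter_complexes(list(good), list()), "empty")
})

test_that("planted rule violations are rejected exactly as planted", {
  set.seed(40)
  drugs <- list(path_fingerprint(molecule_graph(rep("C", 6),
                                                cbind(1:5, 2:6))))
  records <- list()
  truth_keep <- character(0)
  for (i in 1:20) {
    id <- sprintf("rec%02d", i)
    viol <- c("none", "length", "drug_tc")[1 + (i %% 3)]
    rec <- toy_record(
      id,
      n_res = if (viol == "length") sample(c(20, 1200), 1) else sample(50:400, 1),
      lig_elements = if (viol == "drug_tc") rep(c("N", "O"), 3) else rep("C", 6))
    records[[id]] <- rec
    if (viol == "none") truth_keep <- c(truth_keep, id)
  }
  out <- filter_complexes(records, drugs)
  expect_setequal(names(out$records), truth_keep)
})

test_that("global sequence identity behaves on identical, mutated and unrelated pairs", {
  s <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                    80, replace = TRUE), collapse = "")
  expect_equal(sequence_identity(s, s), 1.0)

  # point mutation of 20% of positions, no indels: identity is countable
  # directly as the fraction of unchanged characters
  set.seed(41)
  chars <- strsplit(s, "")[[1]]
  idx <- sample(80, 16)
  chars[idx] <- sample(c("M", "N", "P", "Q", "R"), 16, replace = TRUE)
  mut <- paste(chars, collapse = "")
  direct <- mean(strsplit(s, "")[[1]] == strsplit(mut, "")[[1]])
  expect_gte(direct, 0.8)
  expect_equal(sequence_identity(s, mut), direct, tolerance = 0.02)
})

test_that("greedy sequence clustering recovers planted families", {
  mk <- function(id, seq) {
    r <- toy_record(id)
    r$sequence <- seq
    r
  }
  a <- paste(rep("ACDEFGHIKL", 8), collapse = "")
  expect_equal(length(unique(cluster_sequences(list(mk("x", a), mk("y", a))))),
               1)
  b <- paste(rep("MNPQRSTVWY", 8), collapse = "")
  expect_equal(length(unique(cluster_sequences(list(mk("x", a), mk("y", b))))),
               2)

  # 3 families of 4, each member a 20% point mutant of its family seed
  set.seed(42)
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
             "P", "Q", "R", "S", "T", "V", "W", "Y")
  fams <- lapply(1:3, function(f) paste(sample(alpha, 90, replace = TRUE),
                                        collapse = ""))
  records <- list()
  truth <- integer(0)
  for (f in 1:3) {
    for (m in 1:4) {
      chars <- strsplit(fams[[f]], "")[[1]]
      idx <- sample(90, 18)
      chars[idx] <- sample(alpha, 18, replace = TRUE)
      id <- sprintf("f%dm%d", f, m)
      records[[id]] <- mk(id, paste(chars, collapse = ""))
      truth[id] <- f
    }
  }
  cl <- cluster_sequences(records, 0.40)
  expect_equal(length(unique(cl)), 3)
  expect_equal(length(unique(paste(cl, truth[names(cl)]))), 3)
})

test_that("within-cluster representative selection dedups by ligand and site", {
  same1 <- toy_record("s1", n_res = 70, centre = c(0, 0, 0))
  same2 <- toy_record("s2", n_res = 60, centre = c(1, 0, 0))
  out <- select_representatives(list(same1, same2))
  expect_equal(vapply(out$records, function(r) r$id, ""), "s1",
               ignore_attr = TRUE)
  expect_equal(out$log$rule[out$log$id == "s2"], "redundant_site")

  diff1 <- toy_record("d1", n_res = 70, lig_elements = rep("C", 6))
  diff2 <- toy_record("d2", n_res = 60,
                      lig_elements = c("N", "O", "N", "O", "N", "O"),
                      centre = c(20, 0, 0))
  out2 <- select_representatives(list(diff1, diff2))
  expect_length(out2$records, 2)

  # planted 5-record cluster: keep-set known by construction (the "or"
  # rule keeps a record with a new ligand OR a distant site)
  recs <- list(
    toy_record("k1", n_res = 90, lig_elements = rep("C", 6), centre = c(0, 0, 0)),
    toy_record("k2", n_res = 80, lig_elements = rep(c("N", "O"), 3), centre = c(1, 0, 0)),
    toy_record("k3", n_res = 70, lig_elements = rep("C", 6), centre = c(30, 0, 0)),
    toy_record("x1", n_res = 60, lig_elements = rep("C", 6), centre = c(2, 0, 0)),
    toy_record("x2", n_res = 50, lig_elements = rep(c("N", "O"), 3), centre = c(3, 0, 0))
  )
  out3 <- select_representatives(recs)
  expect_setequal(vapply(out3$records, function(r) r$id, ""),
                  c("k1", "k2", "k3"))
})

test_that("predicted pockets are screened by MCC against the contact truth", {
  rec <- toy_record("r", n_res = 100)
  rec$binding_residues <- rec$residues[1:10, ]
  key <- function(rows) paste(rows$chain, rows$resno, rows$icode, sep = "|")
  truth <- key(rec$binding_residues)

  perfect <- pocket_quality_filter(list(rec), setNames(list(truth), "r"))
  expect_length(perfect$records, 1)
  expect_equal(unname(perfect$mcc["r"]), 1.0)

  disjoint <- pocket_quality_filter(
    list(rec), setNames(list(key(rec$residues[51:60, ])), "r"))
  expect_length(disjoint$records, 0)
  expect_equal(disjoint$log$rule, "pocket_mcc")

  missing <- pocket_quality_filter(list(rec), list())
  expect_equal(missing$log$rule, "missing_prediction")

  # 60% overlap on a 100-residue chain with 10 true binding residues:
  # decide by the direct confusion-count oracle
  pred <- key(rec$residues[c(1:6, 95:98), ])
  tp <- 6; fp <- 4; fn <- 4; tn <- 100 - 14
  mcc <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  got <- pocket_quality_filter(list(rec), setNames(list(pred), "r"))
  expect_equal(unname(got$mcc["r"]), mcc)
  expect_equal(length(got$records) == 1, mcc >= 0.4)
})

test_that("pair enumeration respects ligand clusters and the TM-score ceiling", {
  recs <- lapply(sprintf("r%d", 1:3), toy_record)
  names(recs) <- sprintf("r%d", 1:3)
  cl <- setNames(rep(1L, 3), names(recs))
  tm_all_low <- function(a, b) 0.2
  out <- enumerate_pairs(recs, cl, tm_all_low)
  expect_equal(nrow(out$positive_pairs), 3)   # C(3,2)
  expect_equal(nrow(out$negative_pairs), 0)

  cl2 <- setNames(c(1L, 2L), c("r1", "r2"))
  out2 <- enumerate_pairs(recs[1:2], cl2, function(a, b) 0.9)
  expect_equal(nrow(out2$positive_pairs), 0)
  expect_equal(nrow(out2$negative_pairs), 0)

  # planted 3-cluster manifest with mixed TM-scores vs brute enumeration
  set.seed(43)
  ids <- sprintf("m%02d", 1:7)
  recs3 <- lapply(ids, function(id)
    toy_record(id, n_res = sample(60:90, 1)))
  names(recs3) <- ids
  cl3 <- setNames(c(1L, 1L, 1L, 2L, 2L, 3L, 3L), ids)
  tm_tab <- expand.grid(idA = ids, idB = ids, stringsAsFactors = FALSE)
  tm_tab <- tm_tab[tm_tab$idA < tm_tab$idB, ]
  tm_tab$tm_score <- round(runif(nrow(tm_tab), 0.1, 0.7), 2)
  lookup <- tm_lookup_from_table(tm_tab)
  out3 <- enumerate_pairs(recs3, cl3, lookup)

  # oracle: exhaustive double loop
  want_pos <- character(0)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j && cl3[i] == cl3[j] && lookup(ids[i], ids[j]) < 0.4) {
        want_pos <- c(want_pos, paste(ids[i], ids[j]))
      }
    }
  }
  expect_setequal(paste(out3$positive_pairs$idA, out3$positive_pairs$idB),
                  want_pos)
  nbind <- vapply(recs3, function(r) nrow(r$binding_residues), numeric(1))
  reps <- vapply(split(ids, cl3), function(members)
    members[order(-nbind[members], members)][1], "")
  want_neg <- character(0)
  for (i in seq_along(reps)) {
    for (j in seq_along(reps)) {
      a <- sort(c(reps[i], reps[j]))
      if (i < j && lookup(a[1], a[2]) < 0.4) {
        want_neg <- c(want_neg, paste(a[1], a[2]))
      }
    }
  }
  expect_setequal(paste(out3$negative_pairs$idA, out3$negative_pairs$idB),
                  want_neg)

  # missing TM-scores are skipped and counted
  out4 <- enumerate_pairs(recs, cl, function(a, b) NA_real_)
  expect_equal(nrow(out4$positive_pairs), 0)
  expect_equal(out4$n_skipped, 3)
})

test_that("the full pipeline reproduces planted keep/drop truth and audits clean", {
  set.seed(44)
  drugs <- list(path_fingerprint(molecule_graph(rep("C", 6), cbind(1:5, 2:6))),
                path_fingerprint(molecule_graph(rep(c("N", "O"), 3),
                                                cbind(1:5, 2:6))))
  seqs <- replicate(4, paste(sample(c("A", "C", "D", "E", "F", "G", "H",
                                      "I", "K", "L", "M", "N", "P", "Q",
                                      "R", "S", "T", "V", "W", "Y"),
                                    80, replace = TRUE), collapse = ""))
  mk <- function(id, seq, lig, centre = c(0, 0, 0), n_res = 80) {
    r <- toy_record(id, n_res = n_res, lig_elements = lig, centre = centre)
    r$sequence <- seq
    r
  }
  records <- list(
    mk("a1", seqs[1], rep("C", 6)),                         # keeper
    mk("a2", seqs[2], rep(c("N", "O"), 3), centre = c(40, 0, 0)),  # keeper
    mk("a3", seqs[3], rep("C", 6), centre = c(80, 0, 0)),   # keeper
    mk("short", seqs[4], rep("C", 6), n_res = 30),          # planted: length
    mk("odd", paste(rep("ACDEFGHIKL", 8), collapse = ""),
       rep("S", 6))                                         # planted: drug_tc
  )
  tm_tab <- data.frame(idA = c("a1", "a1", "a2"), idB = c("a2", "a3", "a3"),
                       tm_score = c(0.2, 0.3, 0.8))
  man <- curate_dataset(records, drugs, tm_lookup_from_table(tm_tab))
  expect_setequal(man$complexes, c("a1", "a2", "a3"))
  expect_equal(man$filter_log$rule[man$filter_log$id == "short"], "length")
  expect_equal(man$filter_log$rule[man$filter_log$id == "odd"], "drug_tc")

  # ligand clusters: C-chains together (a1, a3), N/O chain apart
  expect_equal(man$ligand_clusters[["a1"]], man$ligand_clusters[["a3"]])
  expect_false(man$ligand_clusters[["a1"]] == man$ligand_clusters[["a2"]])

  # a1~a3 share a ligand cluster but TM 0.3 < 0.4 -> positive pair;
  # a2~a3 blocked by TM 0.8; a1~a2 negative at TM 0.2
  expect_equal(nrow(man$positive_pairs), 1)
  expect_setequal(c(man$positive_pairs$idA, man$positive_pairs$idB),
                  c("a1", "a3"))
  expect_gte(nrow(man$negative_pairs), 1)

  expect_equal(nrow(verify_manifest(man)), 0)

  # every input record is accounted for: survivor or logged rejection
  seen <- union(man$complexes, man$filter_log$id[man$filter_log$decision == "reject"])
  expect_setequal(seen, vapply(records, function(r) r$id, ""))

  # idempotence: re-curating the survivors changes nothing
  again <- curate_dataset(records[1:3], drugs, tm_lookup_from_table(tm_tab))
  expect_setequal(again$complexes, man$complexes)
  expect_equal(again$positive_pairs, man$positive_pairs)
  expect_equal(again$negative_pairs, man$negative_pairs)
})

test_that("manifest auditing flags injected violations", {
  recs <- lapply(sprintf("r%d", 1:4), toy_record)
  names(recs) <- sprintf("r%d", 1:4)
  cl <- setNames(c(1L, 1L, 2L, 2L), names(recs))
  man <- structure(list(
    complexes = names(recs),
    ligand_clusters = cl,
    positive_pairs = data.frame(idA = "r1", idB = "r2", tm_score = 0.2,
                                stringsAsFactors = FALSE),
    negative_pairs = data.frame(idA = "r1", idB = "r3", tm_score = 0.3,
                                stringsAsFactors = FALSE),
    config = curation_config()), class = "dataset_manifest")
  expect_equal(nrow(verify_manifest(man)), 0)

  bad <- man
  bad$positive_pairs <- rbind(bad$positive_pairs,
                              data.frame(idA = "r1", idB = "r2", tm_score = 0.6))
  v <- verify_manifest(bad)
  expect_true("tm_max" %in% v$rule)
  expect_true("duplicate_pair" %in% v$rule)

  cross <- man
  cross$negative_pairs <- data.frame(idA = "r1", idB = "r2", tm_score = 0.2)
  v2 <- verify_manifest(cross)
  expect_true("cluster_membership" %in% v2$rule)
  expect_true("set_overlap" %in% v2$rule)

  selfp <- man
  selfp$positive_pairs <- data.frame(idA = "r1", idB = "r1", tm_score = 0.2)
  expect_true("self_pair" %in% verify_manifest(selfp)$rule)
})

test_that("manifests serialise to TSV + YAML", {
  recs <- list(toy_record("w1"), toy_record("w2", centre = c(30, 0, 0),
                                            lig_elements = rep(c("N", "O"), 3)))
  drugs <- lapply(recs, fp_of)
  man <- curate_dataset(recs, drugs,
                        function(a, b) 0.2)
  tmp <- withr::local_tempdir()
  write_manifest(man, tmp)
  expect_true(all(file.exists(file.path(
    tmp, c("complexes.tsv", "positive_pairs.tsv", "negative_pairs.tsv",
           "filter_log.tsv", "config.yaml")))))
  cfg <- yaml::read_yaml(file.path(tmp, "config.yaml"))
  expect_equal(cfg$tm_max, 0.4)
  expect_equal(cfg$min_len, 50)
})
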