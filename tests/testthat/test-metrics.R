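contact_df <- function(atoms, groups) {
  data.frame(ligand_atom = atoms, group = groups, stringsAsFactors = FALSE)
}

test_that("contact-overlap coefficient follows its defining ratio", {
  eq4 <- identity_equivalence(6)
  A <- contact_df(c(1, 1, 2, 3), c("I", "V", "II", "III"))
  B6 <- contact_df(c(1, 1, 2, 4, 5, 6), c("I", "VI", "II", "V", "I", "II"))
  # matches: (1,I) and (2,II) -> 2 / min(4, 6)
  expect_equal(ssc(A, B6, eq4), 0.5)

  expect_equal(ssc(A, A, eq4), 1.0)
  expect_equal(ssc(A, contact_df(c(4, 5), c("VII", "VIII")), eq4), 0)
  expect_equal(ssc(A, contact_df(integer(0), character(0)), eq4), 0)
  expect_error(ssc(contact_df(integer(0), character(0)),
                   contact_df(integer(0), character(0)), eq4), "empty")

  # symmetry under swapping profiles together with inverting eq
  pair <- make_complex_pair(61, n_residues = 55, n_pocket = 6)
  inv <- pair$eq
  inv$pairs <- inv$pairs[, c(2, 1)]
  expect_equal(ssc(pair$recA$contacts, pair$recB$contacts, pair$eq),
               ssc(pair$recB$contacts, pair$recA$contacts, inv))
})

test_that("the contact intersection is a maximum matching, not greedy", {
  eq <- identity_equivalence(2)
  # A: (1,I), (1,I); B: (1,I) duplicated on atom 1 -> only one can match
  A <- contact_df(c(1, 1), c("I", "I"))
  B <- contact_df(c(1, 1, 2), c("I", "I", "V"))
  expect_equal(ssc(A, B, eq), 1.0)  # both A contacts match distinct B rows
})

test_that("Kendall tau hits its analytic extremes and matches pair enumeration", {
  expect_equal(kendall_tau(list(posA = 1:10, posB = 21:30))$tau, 1)
  expect_equal(kendall_tau(list(posA = 1:10, posB = 30:21))$tau, -1)

  os <- kendall_tau(list(posA = 1:4, posB = c(1, 2, 4, 3)))
  expect_equal(os$n_C, 5)
  expect_equal(os$n_D, 1)
  expect_equal(os$tau, 4 / 6)

  set.seed(20)
  for (k in 1:10) {
    posA <- sample(100, 12)
    posB <- sample(100, 12)
    got <- kendall_tau(list(posA = posA, posB = posB))
    want <- brute_tau(posA, posB)
    expect_equal(got$n_C, want$nc)
    expect_equal(got$n_D, want$nd)
    expect_equal(got$tau, want$tau)
    # antisymmetry under reversing one side
    expect_equal(kendall_tau(list(posA = posA, posB = -posB))$tau, -got$tau)
    # invariance under strictly monotone renumbering
    expect_equal(kendall_tau(list(posA = 3 * posA + 7, posB = posB^3))$tau,
                 got$tau)
  }

  expect_error(kendall_tau(list(posA = 1, posB = 1)), "at least 2")
})

test_that("tau of a pocket alignment resolves author numbering through the records", {
  pair <- make_complex_pair(62, n_residues = 60, n_pocket = 6)
  os <- kendall_tau(pair$mapping, pair$recA, pair$recB)
  expect_equal(os$tau, 1)  # transplanted pocket keeps sequence order
  flipped <- pair$mapping
  flipped$pairs$resB <- rev(flipped$pairs$resB)
  expect_equal(kendall_tau(flipped, pair$recA, pair$recB)$tau, -1)
})

test_that("Spearman rho follows the rank-difference formula", {
  expect_equal(spearman_rho(1:10, 2 * (1:10) + 3), 1.0)
  expect_equal(spearman_rho(1:10, rev(1:10)), -1.0)
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 3, 2)), 0.5)  # 1 - 12/24
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")

  # formula agrees with Pearson-on-ranks to 1e-12 whenever ranks are unique
  set.seed(21)
  for (k in 1:20) {
    x <- sample(1000, 30)
    y <- sample(1000, 30)
    expect_equal(spearman_rho(x, y), stats::cor(rank(x), rank(y)),
                 tolerance = 1e-12)
  }

  # ties: midranks + Pearson, matching R's own tie-aware Spearman
  x <- c(1, 1, 2, 3, 4)
  y <- c(2, 1, 1, 3, 3)
  expect_equal(spearman_rho(x, y),
               stats::cor(x, y, method = "spearman"))
})

test_that("rank vectors rank best affinity first with midranks for ties", {
  rv <- rank_vector("t1", c(a = -9.1, b = -7.5, c = -8.3))
  expect_equal(rv$ranks, c(1, 3, 2))
  tied <- rank_vector("t1", c(a = -5, b = -5, c = -4))
  expect_equal(tied$ranks, c(1.5, 1.5, 3))
})

test_that("MCC handles its boundary cases and random-prediction null", {
  expect_equal(binary_mcc(10, 0, 10, 0), 1.0)
  expect_equal(binary_mcc(0, 10, 0, 10), -1.0)
  expect_equal(binary_mcc(2, 1, 6, 1), 11 / 21)
  expect_equal(binary_mcc(0, 0, 5, 0), 0)    # degenerate denominator
  expect_error(binary_mcc(0, 0, 0, 0), "zero")
  expect_error(binary_mcc(-1, 0, 1, 0), "negative")

  set.seed(22)
  vals <- replicate(1000, {
    truth <- stats::runif(500) < 0.3
    pred <- stats::runif(500) < 0.5
    binary_mcc(sum(pred & truth), sum(pred & !truth),
               sum(!pred & !truth), sum(!pred & truth))
  })
  expect_lt(mean(abs(vals)), 0.05)
})

test_that("alignment MCC counts residue pairs as classification units", {
  mk <- function(resA, resB) {
    pocket_alignment(data.frame(chainA = "A", resA = resA, icodeA = "",
                                chainB = "B", resB = resB, icodeB = "",
                                stringsAsFactors = FALSE))
  }
  ref <- mk(1:5, 11:15)
  expect_equal(alignment_mcc(ref, ref, 10, 10), 1.0)

  # one reference pair missed, none spurious: oracle by direct counts
  test <- mk(1:4, 11:14)
  tp <- 4; fp <- 0; fn <- 1; tn <- 100 - 5
  expect_equal(alignment_mcc(test, ref, 10, 10),
               (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))

  # disjoint equal-size alignments on a large universe: negative MCC
  disj <- mk(6:10, 16:20)
  tp <- 0; fp <- 5; fn <- 5; tn <- 400 - 10
  want <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(alignment_mcc(disj, ref, 20, 20), want)
  expect_lt(want, 0)

  empty_ref <- pocket_alignment(data.frame(
    chainA = character(0), resA = integer(0), icodeA = character(0),
    chainB = character(0), resB = integer(0), icodeB = character(0)))
  expect_error(alignment_mcc(ref, empty_ref, 5, 5), "empty")
})

test_that("Pearson correlation passes linear and null sanity checks", {
  x <- rnorm(100)
  expect_equal(pearson_cc(x, 2 * x + 1), 1.0)
  expect_equal(pearson_cc(x, -x), -1.0)
  expect_error(pearson_cc(rep(1, 10), 1:10), "constant")
  set.seed(23)
  expect_lt(abs(pearson_cc(rnorm(1000), rnorm(1000))), 0.1)
})

test_that("the meta-predictor is the product of direct score and rank correlation", {
  expect_equal(meta_score(method_score("glosa", 0.6), 0.5)$value, 0.30)
  expect_equal(meta_score(method_score("apoc", 0.73), 1.0)$value, 0.73)
  expect_equal(meta_score(method_score("apoc", 0.0), -0.4)$value, 0.0)
  expect_equal(meta_score(method_score("apoc", 0.5), 0.2)$method, "meta")
  # monotone non-decreasing in each factor over positive ranges
  expect_gte(meta_score(method_score("m", 0.8), 0.7)$value,
             meta_score(method_score("m", 0.6), 0.7)$value)
  expect_error(meta_score(method_score("m", NA_real_), 0.5), "missing")
})

test_that("the pairwise Spearman matrix is symmetric with unit diagonal", {
  rm_ <- make_rank_matrix(200, 4, planted_rho = 0.8, weight_coupling = 0.3,
                          seed = 24)
  m <- spearman_matrix(rm_$scores)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(1, 4), ignore_attr = TRUE)
  expect_gt(m[1, 2], m[1, 3])  # planted pair beats cross-pair coupling
})
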