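rooted_quartet <- function() {
  # ((a,b),(c,d)) rooted
  ape::read.tree(text = "((a,b),(c,d));")
}

test_that("fitch_score handles forced single and double origins", {
  m <- matrix(c(0, 0, 1, 1), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), "m1"))
  expect_equal(fitch_score(rooted_quartet(), m), 1)
  m2 <- matrix(c(0, 1, 0, 1), 4, 1,
               dimnames = list(c("a", "b", "c", "d"), "m1"))
  expect_equal(fitch_score(rooted_quartet(), m2), 2)
  expect_equal(fitch_score(rooted_quartet(), cbind(m, m2)), 3)
  m0 <- matrix(1, 4, 2, dimnames = list(c("a", "b", "c", "d"), NULL))
  expect_equal(fitch_score(rooted_quartet(), m0), 0)
  expect_error(fitch_score(rooted_quartet(), m[1:3, , drop = FALSE]),
               "not in matrix")
})

test_that("fitch_score equals the exhaustive ancestral-state oracle", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    tips <- paste0("s", seq_len(n))
    nested <- tips[1]
    for (tp in tips[-1]) {
      cands <- cryptclock:::insertions(nested, tp)
      nested <- cands[[sample(length(cands), 1)]]
    }
    states <- stats::setNames(sample(c(0L, 1L, NA), n, TRUE,
                                     prob = c(.4, .4, .2)), tips)
    enc <- cryptclock:::encode_states(matrix(states, n, 1,
                                             dimnames = list(tips, "c")))
    if (!is.list(nested)) next
    got <- cryptclock:::fitch_score_nested(nested, enc)
    want <- brute_min_changes(nested, as.list(states))
    expect_equal(got, want)
  }
})

test_that("search recovers simulated noise-free topologies", {
  cfg <- sim_config(n_patients_per_arm = 1, biopsies_np = c(1L, 1L),
                    crypts_per_biopsy = 4L, p_fn = 0, spurious_rate = 0,
                    unique_events = TRUE, scramble_phase = FALSE,
                    lambda_np = 0.01)
  sim <- simulate_patient(cfg, "X", FALSE, seed = 31)
  crypts <- sim$samples$sample_id[sim$samples$role == "crypt"]
  cm <- build_character_matrix(sim$truth$profiles[crypts])
  res <- search_parsimony(cm$matrix, "heuristic", n_restarts = 10, seed = 1)
  tr <- assign_branch_lengths(res$tree, cm$matrix)
  for (s in crypts)
    expect_equal(distance_from_normal(tr, s),
                 count_markers_independent(sim$truth$profiles[[s]]))
})

test_that("fitch_score agrees with phangorn as an external oracle", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  for (i in 1:5) {
    n <- sample(4:8, 1); k <- sample(8:20, 1)
    m <- matrix(rbinom(n * k, 1, 0.35), n, k,
                dimnames = list(paste0("s", 1:n), NULL))
    tr <- search_parsimony(m, "heuristic", n_restarts = 3, seed = i)$tree
    pd <- phangorn::phyDat(rbind(m, normal = 0L), type = "USER",
                           levels = c(0, 1))
    expect_equal(fitch_score(tr, m),
                 as.integer(phangorn::parsimony(ape::unroot(tr), pd)))
  }
})

test_that("3 samples give the single rooted topology", {
  m <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), NULL))
  res <- search_parsimony(m, "exhaustive")
  expect_s3_class(res$tree, "phylo")
  expect_setequal(res$tree$tip.label, c("a", "b", "c", "normal"))
  expect_error(search_parsimony(matrix(0, 12, 2,
    dimnames = list(paste0("s", 1:12), NULL)), "exhaustive"), "exhaustive")
})

test_that("branch lengths conserve the Fitch score, ACCTRAN and DELTRAN", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(4:8, 1); k <- sample(5:15, 1)
    m <- matrix(rbinom(n * k, 1, 0.4), n, k,
                dimnames = list(paste0("s", 1:n), NULL))
    res <- search_parsimony(m, "heuristic", n_restarts = 3, seed = i)
    for (mode in c("acctran", "deltran")) {
      bl <- assign_branch_lengths(res$tree, m, mode)
      expect_equal(sum(bl$edge.length), fitch_score(res$tree, m))
    }
  }
  # 1-character single origin -> exactly one branch of length 1
  m1 <- matrix(c(0, 0, 1, 1), 4, 1,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  tr <- ape::read.tree(text = "(((c,d),(a,b)),normal);")
  bl <- assign_branch_lengths(tr, m1)
  expect_equal(sum(bl$edge.length), 1)
  expect_equal(sum(bl$edge.length == 1), 1)
})

test_that("patristic distances and diversity follow the metric identities", {
  tr <- ape::read.tree(text = "((a:2,b:3):1,(c:1,normal:0):2);")
  expect_equal(patristic_distance(tr, "a", "a"), 0)
  expect_equal(patristic_distance(tr, "a", "b"), 5)
  expect_equal(patristic_distance(tr, "a", "c"), 6)
  expect_equal(distance_from_normal(tr, "b"), 6)
  expect_error(patristic_distance(tr, "a", "zz"), "unknown tip")
  expect_equal(diversity(tr, c("a", "b")), 5)
  expect_equal(diversity(tr, c("a", "b", "c")), mean(c(5, 6, 7)))
  expect_error(diversity(tr, "a"), "two samples")
  # oracle: brute-force path sums on random trees
  set.seed(3)
  for (i in 1:5) {
    rt <- ape::rtree(6)
    d1 <- patristic_matrix(rt)
    d2 <- as.matrix(stats::cophenetic(rt))[rownames(d1), colnames(d1)]
    expect_lt(max(abs(d1 - d2)), 1e-12)
  }
})
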