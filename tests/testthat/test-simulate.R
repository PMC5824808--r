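test_that("the default cohort matches the sampling design", {
  cfg <- sim_config(lambda_np = 0.002, lambda_p = 0.004)  # light for speed
  res <- simulate_cohort(cfg, seed = 2)
  expect_length(res, 8)
  # 612 samples: 4 x 54 non-progressor + 4 x 99 progressor
  expect_equal(sum(vapply(res, function(r) length(r$profiles), 0L)), 612)
  np <- res[[1]]
  expect_equal(sum(np$samples$role == "crypt"), 48)
  expect_equal(sum(np$samples$role == "biopsy_epithelium"), 6)
  pr <- res[[5]]
  expect_true(pr$patients$progressor)
  expect_equal(sum(pr$samples$role == "crypt"), 88)
  expect_equal(sum(pr$samples$role == "biopsy_epithelium"), 11)
  # nine samples per biopsy
  per_bio <- table(np$samples$biopsy_id)
  expect_true(all(per_bio == 9))
})

test_that("a rate of zero with no founder events leaves genomes diploid", {
  cfg <- sim_config(n_patients_per_arm = 1, biopsies_np = c(1L, 1L),
                    lambda_np = 0, founder_events = 0L, p_fn = 0,
                    spurious_rate = 0)
  sim <- simulate_patient(cfg, "X", FALSE, seed = 5)
  for (p in sim$profiles) {
    expect_true(all(p$cn1 == 1))
    expect_true(all(p$cn2 == 1))
  }
})

test_that("branch event counts follow the Poisson expectation", {
  # rate = lambda x 2 alleles x loci per year on every branch (no gradient)
  cfg <- sim_config(n_patients_per_arm = 1, biopsies_np = c(1L, 0L),
                    crypts_per_biopsy = 4L, gej_beta = 0, p_fn = 0,
                    spurious_rate = 0, founder_events = 0L,
                    lambda_np = 0.004, Ne_tau = 2)
  tot <- 0
  expected <- 0
  for (r in 1:60) {
    sim <- simulate_patient(cfg, "X", FALSE, seed = 400 + r)
    tot <- tot + nrow(sim$truth$events)
    ct <- sim$truth$tree
    dt <- ct$age - ct$age[ifelse(ct$parent == 0, NA, ct$parent)]
    expected <- expected + 0.004 * 2 * 100 * sum(dt, na.rm = TRUE)
  }
  se <- sqrt(expected)
  expect_lt(abs(tot - expected), 3 * se)
})

test_that("degrade drops and fabricates events as configured", {
  grid <- tiny_grid()
  founder <- matrix(1L, 10, 2)
  p <- profile_from_states(grid, c(1, 0, 1, 2, 1, 1, 1, 1, 1, 1),
                           rep(1, 10), "c1")
  # identity at zero noise
  out0 <- degrade(list(c1 = p), p_fn = 0, spurious_rate = 0,
                  founder = founder, seed = 1)
  expect_equal(out0$c1$cn1, p$cn1)
  # p_fn = 1 reverts to the founder state
  out1 <- degrade(list(c1 = p), p_fn = 1, spurious_rate = 0,
                  founder = founder, seed = 1)
  expect_true(all(out1$c1$cn1 == 1) && all(out1$c1$cn2 == 1))
  # dropout fraction matches the binomial expectation
  set.seed(2)
  many <- lapply(seq_len(300), function(i) {
    cn1 <- rep(1L, 10)
    cn1[sample(10, 4)] <- 0L
    profile_from_states(grid, cn1, rep(1, 10), paste0("c", i))
  })
  names(many) <- paste0("c", seq_along(many))
  noisy <- degrade(many, p_fn = 0.3, spurious_rate = 0, founder = founder,
                   seed = 3)
  dropped <- sum(vapply(seq_along(many), function(i)
    sum(noisy[[i]]$cn1 == 1 & many[[i]]$cn1 == 0), 0))
  n_ev <- 4 * 300
  expect_lt(abs(dropped - 0.3 * n_ev), 3 * sqrt(n_ev * 0.3 * 0.7))
  # spurious events appear at the stated rate
  clean <- lapply(seq_len(200), function(i)
    profile_from_states(grid, rep(1, 10), rep(1, 10), paste0("s", i)))
  names(clean) <- paste0("s", seq_along(clean))
  sp <- degrade(clean, p_fn = 0, spurious_rate = 0.5, founder = founder,
                seed = 4)
  n_sp <- sum(vapply(sp, function(p) sum(p$cn1 != 1) + sum(p$cn2 != 1), 0))
  expect_lt(abs(n_sp - 100), 3 * sqrt(100))
})

test_that("biopsy consensus keeps events carried by >= f of its crypts", {
  cfg <- sim_config(n_patients_per_arm = 1, biopsies_np = c(1L, 0L),
                    p_fn = 0, spurious_rate = 0, unique_events = TRUE,
                    f_consensus = 0.5, lambda_np = 0.01,
                    scramble_phase = FALSE)
  sim <- simulate_patient(cfg, "X", FALSE, seed = 17)
  epi <- grep("epi", names(sim$truth$sample_events), value = TRUE)
  crypts <- setdiff(names(sim$truth$sample_events), epi)
  carried <- table(unlist(sim$truth$sample_events[crypts]))
  expect_setequal(sim$truth$sample_events[[epi]],
                  as.integer(names(carried)[carried >= 4]))
})

test_that("outputs are bit-identical for a fixed seed", {
  cfg <- sim_config(n_patients_per_arm = 1, biopsies_np = c(1L, 1L),
                    lambda_np = 0.005)
  a <- simulate_patient(cfg, "X", FALSE, seed = 9)
  b <- simulate_patient(cfg, "X", FALSE, seed = 9)
  expect_identical(lapply(a$profiles, as.data.frame),
                   lapply(b$profiles, as.data.frame))
  expect_identical(a$truth$events, b$truth$events)
})

test_that("ctmc event mode produces valid profiles", {
  cfg <- sim_config(n_patients_per_arm = 1, biopsies_np = c(1L, 0L),
                    crypts_per_biopsy = 4L, event_mode = "ctmc",
                    lambda_np = 0.01)
  sim <- simulate_patient(cfg, "X", FALSE, seed = 23)
  expect_length(sim$profiles, 5)
  for (p in sim$profiles) expect_true(validate_profile(p, cfg$grid))
})
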