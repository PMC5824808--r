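test_that("HPD, posterior summaries and ESS behave on known samples", {
  x <- posterior_trace(data.frame(p = rep(3.5, 100)))
  s <- summarize_posterior(x, "p")
  expect_equal(s$mean, 3.5)
  expect_equal(s$hpd, c(3.5, 3.5))
  set.seed(1)
  z <- stats::rnorm(1e5)
  tz <- posterior_trace(data.frame(z = z))
  s2 <- summarize_posterior(tz, "z")
  expect_lt(abs(s2$hpd[1] + 1.96), 0.05)
  expect_lt(abs(s2$hpd[2] - 1.96), 0.05)
  expect_gt(s2$ess, 0.8 * 1e5)          # iid samples: ESS ~ n
  expect_lt(s2$ess, 1.2 * 1e5)
  expect_error(summarize_posterior(tz, "nope"), "not in trace")
  expect_error(summarize_posterior(posterior_trace(data.frame(a = 1)[0, ,
    drop = FALSE]), "a"), "empty")
})

test_that("posterior overlap matches closed forms", {
  set.seed(2)
  a <- stats::rnorm(1e5)
  expect_gt(posterior_overlap(data.frame(x = a), data.frame(x = a), "x"),
            0.98)
  b <- stats::rnorm(1e5, 50)
  expect_lt(posterior_overlap(data.frame(x = a), data.frame(x = b), "x"),
            0.01)
  # OVL of N(0,1) vs N(2,1) = 2*pnorm(-1)
  c2 <- stats::rnorm(1e5, 2)
  ovl <- posterior_overlap(data.frame(x = a), data.frame(x = c2), "x")
  expect_lt(abs(ovl - 2 * stats::pnorm(-1)), 0.02)
  expect_error(posterior_overlap(data.frame(x = a), data.frame(y = 1), "x"),
               "missing")
})

test_that("the sampler is reproducible and reports diagnostics", {
  set.seed(99)
  ages <- stats::setNames(rep(c(60, 62), each = 3), paste0("t", 1:6))
  ct <- sim_coalescent_tree(ages, 3)
  cn <- sim_cn_on_tree(ct, n_loci = 10, lambda = 0.02, rho = 0.5, K = 4,
                       root_age = min(ct$age) - 1)
  cfg <- clock_config(n_steps = 800, burnin_frac = 0.25, thin = 5)
  f1 <- mcmc_run(cn, cfg, seed = 7)
  f2 <- mcmc_run(cn, cfg, seed = 7)
  expect_identical(as.data.frame(f1$trace), as.data.frame(f2$trace))
  expect_true(all(c("lambda", "rho", "Ne_tau", "root_age", "gd_rate",
                    "log_likelihood", "log_posterior") %in%
                  names(f1$trace)))
  expect_true(all(is.finite(as.matrix(f1$trace))))
  expect_named(f1$ess)
  expect_true(all(f1$acceptance[!is.na(f1$acceptance)] >= 0))
  # root_age never exceeds the age at first sampling
  expect_lt(max(f1$trace$root_age), min(ages) + 1e-9)
  expect_error(mcmc_run(cn, clock_config(n_steps = 0)), "chain")
})

test_that("key=value config files round into clock_config", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# chain", "n_steps = 5000", "thin = 10",
               "clock_mode = rlc", "lambda_range = 1e-4, 0.5"), path)
  cfg <- read_clock_config(path)
  expect_equal(cfg$n_steps, 5000L)
  expect_equal(cfg$clock_mode, "rlc")
  expect_equal(cfg$lambda_range, c(1e-4, 0.5))
  writeLines("nonsense_key = 1", path)
  expect_error(read_clock_config(path), "unknown config keys")
})

test_that("onset age summarises root_age on the patient-age axis", {
  tr <- posterior_trace(data.frame(root_age = c(40, 41, 42, 43)))
  s <- onset_age(tr)
  expect_equal(s$mean, 41.5)
  expect_equal(s$hpd, c(40, 43))
})

test_that("consensus annotation reports strict-clock rates and clades", {
  set.seed(4)
  ages <- stats::setNames(rep(60, 4), letters[1:4])
  ct <- sim_coalescent_tree(ages, 2)
  cn <- sim_cn_on_tree(ct, n_loci = 20, lambda = 0.05, rho = 0.5, K = 4,
                       root_age = ct$age[ct$root] - 2)
  fit <- mcmc_run(cn, clock_config(n_steps = 3000, burnin_frac = 0.2,
                                   thin = 5), seed = 3)
  ann <- annotate_rate_changes(fit)
  expect_s3_class(ann$tree, "phylo")
  nodes_ann <- attr(ann$tree, "node_annotations")
  post <- nodes_ann$posterior[!is.na(nodes_ann$posterior)]
  expect_true(all(post >= 0 & post <= 1))
  # tips are always present: posterior 1
  expect_true(all(abs(nodes_ann$posterior[1:4] - 1) < 1e-12))
  # strict clock: every branch mean rate equals the posterior lambda mean
  tipsr <- nodes_ann$rate[1:4]
  expect_lt(max(abs(tipsr - mean(fit$trace$lambda))), 1e-9)
  expect_error(annotate_rate_changes(list(trees = fit$trees[1:5])),
               "100")
})
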