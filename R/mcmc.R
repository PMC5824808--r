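#' Configuration for the Bayesian copy-number clock
#'
#' Priors (the substitution and clock models are documented in the package
#' vignette): `lambda` log-uniform on `[1e-5, 1]` events/allele copy/locus/
#' year; `rho` uniform on `[0, 1]`; `Ne_tau` log-uniform on `[0.1, 1000]`
#' years; the root (unaltered-ancestor) age uniform on the 60 years before
#' the earliest sampling age; the genome-doubling rate log-uniform on
#' `[1e-5, 1]` per year; under the random local clock, a Poisson(ln 2) prior
#' on the number of rate changes and log-normal(0, 1) multipliers.
#'
#' @param n_steps Total Metropolis-Hastings steps (default 2e6; tests use
#'   far shorter chains).
#' @param burnin_frac Fraction of the chain discarded.
#' @param thin Keep one sample every `thin` steps.
#' @param clock_mode `"strict"` or `"rlc"`.
#' @param K Copy-number cap.
#' @param lambda_range,ne_range,gd_range Log-uniform prior bounds.
#' @param root_age_span Width (years) of the uniform root-age prior below
#'   the earliest sampling age.
#' @param rlc_expected,rlc_sigma Random-local-clock prior parameters.
#' @param move_weights Named numeric vector overriding the default relative
#'   move weights (`lambda`, `rho`, `ne`, `root_age`, `gd`, `node_slide`,
#'   `exchange`, `updown`, `prior_draw`, and in RLC mode `ind_flip`,
#'   `mult_scale`). A sampler-efficiency knob only; the target posterior is
#'   unchanged.
#' @return A `clock_config` list.
#' @export
clock_config <- function(n_steps = 2e6, burnin_frac = 0.1, thin = 1000,
                         clock_mode = c("strict", "rlc"), K = 4L,
                         lambda_range = c(1e-5, 1),
                         ne_range = c(0.1, 1000),
                         gd_range = c(1e-5, 1),
                         root_age_span = 60,
                         rlc_expected = log(2), rlc_sigma = 1,
                         move_weights = NULL) {
  clock_mode <- match.arg(clock_mode)
  if (n_steps < 1 || burnin_frac < 0 || burnin_frac >= 1 || thin < 1)
    stop("invalid chain configuration")
  structure(list(n_steps = as.integer(n_steps), burnin_frac = burnin_frac,
                 thin = as.integer(thin), clock_mode = clock_mode,
                 K = as.integer(K), lambda_range = lambda_range,
                 ne_range = ne_range, gd_range = gd_range,
                 root_age_span = root_age_span,
                 rlc_expected = rlc_expected, rlc_sigma = rlc_sigma,
                 move_weights = move_weights),
            class = "clock_config")
}

#' Data-driven starting tree for the clock sampler
#'
#' Average-linkage clustering of the copy-number states (Manhattan distance)
#' converted into a time-calibrated tree respecting the sampling ages: each
#' internal node is placed just below its children, deeper for larger
#' cluster heights. A sampler initialisation device only — the posterior
#' does not depend on it.
#'
#' @param cn A `cn_matrix`.
#' @param depth_scale Years of tree depth per unit of normalised cluster
#'   height.
#' @return An internal clock tree.
#' @export
upgma_start_tree <- function(cn, depth_scale = 5) {
  ids <- dimnames(cn$states)[[1]]
  n <- length(ids)
  m <- cbind(cn$states[, , 1], cn$states[, , 2])
  m[is.na(m)] <- 1L
  d <- stats::dist(m, method = "manhattan")
  hc <- stats::hclust(d, method = "average")
  hmax <- max(hc$height, 1e-9)
  parent <- integer(2L * n - 1L)
  age <- c(cn$ages[ids], numeric(n - 1L))
  node_of <- integer(n - 1L)   # hclust merge row -> clock node
  hprev <- numeric(2L * n - 1L)
  for (i in seq_len(n - 1L)) {
    v <- n + i
    ch <- vapply(hc$merge[i, ], function(x)
      if (x < 0) -x else node_of[x], 0L)
    dh <- vapply(hc$merge[i, ], function(x)
      if (x < 0) 0 else hc$height[x] , 0)
    gap <- max((hc$height[i] - max(dh)) / hmax * depth_scale, 0.05)
    age[v] <- min(age[ch]) - gap
    parent[ch] <- v
    node_of[i] <- v
  }
  list(tip_label = ids, parent = parent, age = age, root = 2L * n - 1L)
}

#' Read a clock configuration from a key=value file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments;
#' keys are the arguments of [clock_config()], with two-element ranges
#' written comma-separated (e.g. `lambda_range = 1e-5, 1`).
#'
#' @param path File path.
#' @return A `clock_config`.
#' @export
read_clock_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    args[[key]] <- if (key == "clock_mode") val else as.numeric(val)
  }
  unknown <- setdiff(names(args), names(formals(clock_config)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ","))
  do.call(clock_config, args)
}

log_unif_lp <- function(x, range) {
  if (x < range[1] || x > range[2]) return(-Inf)
  -log(x)
}

clock_log_prior <- function(st, ct, cfg, root_bounds) {
  lp <- log_unif_lp(st$lambda, cfg$lambda_range) +
    log_unif_lp(st$Ne_tau, cfg$ne_range) +
    log_unif_lp(st$gd_rate, cfg$gd_range)
  if (st$rho < 0 || st$rho > 1) return(-Inf)
  if (st$root_age < root_bounds[1] || st$root_age > root_bounds[2])
    return(-Inf)
  if (st$root_age > ct$age[ct$root]) return(-Inf)
  n <- length(ct$tip_label)
  lp <- lp + coalescent_log_prior_times(
    max(ct$age) - ct$age[seq_len(n)],
    max(ct$age) - ct$age[-seq_len(n)], st$Ne_tau)
  if (cfg$clock_mode == "rlc") {
    nr <- setdiff(seq_along(ct$parent), ct$root)
    lp <- lp + rlc_log_prior(st$ind[nr], st$mult[nr],
                             cfg$rlc_expected, cfg$rlc_sigma)
  }
  lp
}

#' Run the Metropolis-Hastings sampler for the copy-number clock
#'
#' Jointly samples the SCA rate `lambda`, gain fraction `rho`, coalescent
#' scale `Ne_tau`, unaltered-ancestor age `root_age`, genome-doubling rate
#' `gd_rate`, the time-calibrated tree (node ages and topology via uniform
#' node slides and narrow exchange) and, in `rlc` mode, per-branch rate
#' change indicators and multipliers.
#'
#' @param cn A `cn_matrix`.
#' @param config A [clock_config()].
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param init_tree Optional starting tree (a rooted `phylo` with branch
#'   lengths in years whose tips match `cn`); default is a draw from the
#'   coalescent prior.
#' @return List of class `clock_fit`: `trace` (a `posterior_trace` of
#'   retained samples), `trees` (retained tree states with per-branch
#'   effective rates), `acceptance` (per-move rates), `ess` (per parameter),
#'   `config`.
#' @export
mcmc_run <- function(cn, config = clock_config(), seed = 1L,
                     init_tree = NULL) {
  set.seed(seed)
  cfg <- config
  ages <- cn$ages
  n <- length(ages)
  if (n < 3) stop("need >= 3 samples")
  earliest <- min(ages)
  root_bounds <- c(earliest - cfg$root_age_span, earliest)

  # initial state from the prior (or the supplied tree)
  if (!is.null(init_tree)) {
    ct <- if (inherits(init_tree, "phylo"))
      phylo_to_clock_tree(init_tree, ages) else init_tree
  } else if (dim(cn$states)[2] > 0) {
    ct <- upgma_start_tree(cn)
  } else {
    ct <- NULL
    for (try in 1:200) {
      ct <- sim_coalescent_tree(ages, stats::runif(1, 2, 20))
      if (ct$age[ct$root] > root_bounds[1]) break
    }
  }
  if (ct$age[ct$root] <= root_bounds[1])
    stop("could not initialise a tree inside the root-age prior")
  nv <- length(ct$parent)
  st <- list(
    lambda = exp(mean(log(cfg$lambda_range))),
    rho = 0.5,
    Ne_tau = exp(mean(log(cfg$ne_range))),
    gd_rate = exp(mean(log(cfg$gd_range))),
    root_age = (max(root_bounds[1], ct$age[ct$root] - 10) +
                min(root_bounds[2], ct$age[ct$root])) / 2,
    ind = rep(0L, nv), mult = rep(1, nv))
  if (st$root_age >= ct$age[ct$root])
    st$root_age <- (root_bounds[1] + ct$age[ct$root]) / 2

  eg_cache_rho <- NA_real_
  eg <- NULL
  tipL <- cn_tip_partials(cn, ct$tip_label)
  loglik <- function(ct, st) {
    if (is.na(eg_cache_rho) || st$rho != eg_cache_rho) {
      eg <<- generator_eigen(build_generator(cn$K, 1, st$rho))
      eg_cache_rho <<- st$rho
    }
    clock_log_likelihood(ct, cn, list(
      lambda = st$lambda, rho = st$rho, root_age = st$root_age,
      gd_rate = st$gd_rate, rlc_indicators = st$ind,
      rlc_multipliers = st$mult), eg = eg, tipL = tipL)
  }
  cur_ll <- loglik(ct, st)
  cur_lp <- clock_log_prior(st, ct, cfg, root_bounds)
  if (!is.finite(cur_ll + cur_lp)) stop("invalid initial state")

  moves <- c(lambda = 3, rho = 1, ne = 2, root_age = 1, gd = 1,
             node_slide = 5, exchange = 3, updown = 3, prior_draw = 2)
  if (cfg$clock_mode == "rlc")
    moves <- c(moves, ind_flip = 3, mult_scale = 2)
  if (!is.null(cfg$move_weights)) {
    bad <- setdiff(names(cfg$move_weights), names(moves))
    if (length(bad)) stop("unknown move weights: ", paste(bad, collapse = ","))
    moves[names(cfg$move_weights)] <- cfg$move_weights
    moves <- moves[moves > 0]
  }
  acc <- att <- stats::setNames(numeric(length(moves)), names(moves))
  move_names <- names(moves)
  move_prob <- moves / sum(moves)

  keep_from <- ceiling(cfg$n_steps * cfg$burnin_frac)
  rows <- list()
  trees <- list()
  internals <- setdiff(seq_len(nv), seq_len(n))
  nonroot <- function(ct) setdiff(seq_len(nv), ct$root)

  for (step in seq_len(cfg$n_steps)) {
    mv <- sample(move_names, 1, prob = move_prob)
    att[mv] <- att[mv] + 1
    new_ct <- ct
    new_st <- st
    log_h <- 0
    ok <- TRUE
    if (mv == "lambda" || mv == "ne" || mv == "gd") {
      f <- exp(stats::runif(1, -0.7, 0.7))
      fld <- c(lambda = "lambda", ne = "Ne_tau", gd = "gd_rate")[[mv]]
      new_st[[fld]] <- st[[fld]] * f
      log_h <- log(f)
    } else if (mv == "rho") {
      x <- st$rho + stats::rnorm(1, 0, 0.1)
      while (x < 0 || x > 1) x <- if (x < 0) -x else 2 - x
      new_st$rho <- x
    } else if (mv == "root_age") {
      hi <- min(root_bounds[2], ct$age[ct$root])
      # alternate a window-wide draw with a local random walk
      new_st$root_age <- if (stats::runif(1) < 0.5)
        stats::runif(1, root_bounds[1], hi)
      else st$root_age + stats::rnorm(1, 0, 1.5)
      if (new_st$root_age < root_bounds[1] || new_st$root_age > hi)
        ok <- FALSE
    } else if (mv == "node_slide") {
      v <- if (length(internals) == 1) internals
           else sample(internals, 1)
      kids <- which(ct$parent == v)
      hi <- min(ct$age[kids])
      lo <- if (v == ct$root) st$root_age
            else ct$age[ct$parent[v]]
      new_ct$age[v] <- stats::runif(1, lo, hi)
    } else if (mv == "exchange") {
      cand <- internals[internals != ct$root]
      if (!length(cand)) ok <- FALSE
      else {
        cnode <- if (length(cand) == 1) cand else sample(cand, 1)
        p <- ct$parent[cnode]
        sib <- setdiff(which(ct$parent == p), cnode)
        kids <- which(ct$parent == cnode)
        x <- if (length(kids) == 1) kids else sample(kids, 1)
        if (ct$age[sib] <= ct$age[cnode]) ok <- FALSE
        else {
          new_ct$parent[x] <- p
          new_ct$parent[sib] <- cnode
        }
      }
    } else if (mv == "ind_flip") {
      b <- sample(nonroot(ct), 1)
      k <- sum(st$ind[nonroot(ct)])
      B <- nv - 1L
      if (st$ind[b] == 0L) {
        new_st$ind[b] <- 1L
        new_st$mult[b] <- stats::rlnorm(1, 0, cfg$rlc_sigma)
        # proposal density of the new multiplier cancels against its prior;
        # remaining ratio is the Poisson/placement prior handled in
        # clock_log_prior, so correct for the prior-density cancellation:
        log_h <- -stats::dlnorm(new_st$mult[b], 0, cfg$rlc_sigma, log = TRUE)
      } else {
        log_h <- stats::dlnorm(st$mult[b], 0, cfg$rlc_sigma, log = TRUE)
        new_st$ind[b] <- 0L
        new_st$mult[b] <- 1
      }
    } else if (mv == "prior_draw") {
      # independence proposal from the prior for one scalar parameter;
      # prior and proposal densities cancel, acceptance = likelihood ratio
      which_p <- sample(c("lambda", "rho", "Ne_tau", "gd_rate", "root_age"), 1)
      if (which_p == "rho") {
        new_st$rho <- stats::runif(1)
      } else if (which_p == "root_age") {
        hi <- min(root_bounds[2], ct$age[ct$root])
        new_st$root_age <- stats::runif(1, root_bounds[1], hi)
      } else {
        rng <- switch(which_p, lambda = cfg$lambda_range,
                      Ne_tau = cfg$ne_range, gd_rate = cfg$gd_range)
        new_st[[which_p]] <- exp(stats::runif(1, log(rng[1]), log(rng[2])))
        log_h <- log(new_st[[which_p]]) - log(st[[which_p]])
      }
    } else if (mv == "updown") {
      # joint rate-up / tree-down scaling about the latest tip age: breaks
      # the lambda x tree-height correlation
      f <- exp(stats::runif(1, -0.5, 0.5))
      a_max <- max(ct$age[seq_len(n)])
      new_ct$age[-seq_len(n)] <- a_max - (a_max - ct$age[-seq_len(n)]) / f
      new_st$lambda <- st$lambda * f
      new_st$Ne_tau <- st$Ne_tau / f
      new_st$root_age <- a_max - (a_max - st$root_age) / f
      bad <- FALSE
      for (v in internals) {
        kids <- which(new_ct$parent == v)
        if (any(new_ct$age[kids] <= new_ct$age[v])) { bad <- TRUE; break }
      }
      if (bad) ok <- FALSE
      log_h <- log(f) - (length(internals) + 2) * log(f)
    } else if (mv == "mult_scale") {
      active <- which(st$ind == 1L)
      if (!length(active)) ok <- FALSE
      else {
        b <- if (length(active) == 1) active else sample(active, 1)
        f <- exp(stats::runif(1, -0.5, 0.5))
        new_st$mult[b] <- st$mult[b] * f
        log_h <- log(f)
      }
    }
    if (ok) {
      new_lp <- clock_log_prior(new_st, new_ct, cfg, root_bounds)
      if (is.finite(new_lp)) {
        new_ll <- loglik(new_ct, new_st)
        if (log(stats::runif(1)) <
            (new_ll + new_lp) - (cur_ll + cur_lp) + log_h) {
          ct <- new_ct; st <- new_st
          cur_ll <- new_ll; cur_lp <- new_lp
          acc[mv] <- acc[mv] + 1
        }
      }
    }
    if (step > keep_from && step %% cfg$thin == 0L) {
      nr <- setdiff(seq_len(nv), ct$root)
      rows[[length(rows) + 1L]] <- c(
        step = step, log_posterior = cur_ll + cur_lp,
        log_likelihood = cur_ll, lambda = st$lambda, rho = st$rho,
        Ne_tau = st$Ne_tau, root_age = st$root_age, gd_rate = st$gd_rate,
        t_mrca = ct$age[ct$root], n_rate_changes = sum(st$ind[nr]))
      trees[[length(trees) + 1L]] <- list(
        ct = ct, eff_rate = st$lambda * rlc_effective(ct, st$ind, st$mult),
        ind = st$ind)
    }
  }
  tracedf <- as.data.frame(do.call(rbind, rows))
  trace <- posterior_trace(tracedf, thin = cfg$thin,
                           burnin_frac = cfg$burnin_frac)
  pars <- c("lambda", "rho", "Ne_tau", "root_age", "gd_rate")
  ess <- vapply(pars, function(p) effective_sample_size(tracedf[[p]]), 0)
  structure(list(trace = trace, trees = trees,
                 acceptance = ifelse(att > 0, acc / att, NA),
                 ess = ess, config = cfg, seed = seed),
            class = "clock_fit")
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf("clock_fit: %d retained samples (%s clock)\n",
              nrow(x$trace), x$config$clock_mode))
  s <- summarize_posterior(x$trace, "lambda")
  cat(sprintf("  lambda: mean %.4g, 95%% HPD [%.4g, %.4g], ESS %.0f\n",
              s$mean, s$hpd[1], s$hpd[2], s$ess))
  invisible(x)
}

#' Effective sample size
#'
#' Autocorrelation-time estimator using Geyer's initial positive sequence.
#'
#' @param x Numeric vector of MCMC samples.
#' @return Estimated effective sample size.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2, 1000), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # sum consecutive pairs until a pair sum goes non-positive
  s <- 0
  k <- 2
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

#' Highest posterior density interval
#'
#' Shortest interval containing a given posterior mass.
#'
#' @param x Numeric samples.
#' @param prob Mass (default 0.95).
#' @return Length-2 numeric vector.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Summarise one posterior parameter
#'
#' @param trace A `posterior_trace` (burn-in already removed).
#' @param parameter Column name.
#' @param prob HPD mass.
#' @return List with `mean`, `hpd` (length 2), `ess`.
#' @export
summarize_posterior <- function(trace, parameter, prob = 0.95) {
  if (!nrow(trace)) stop("empty trace")
  if (!parameter %in% names(trace))
    stop("parameter '", parameter, "' not in trace")
  x <- trace[[parameter]]
  list(mean = mean(x), hpd = hpd_interval(x, prob),
       ess = effective_sample_size(x))
}

#' Overlap of two posterior distributions
#'
#' The overlapping coefficient: the integral of the pointwise minimum of two
#' Gaussian kernel density estimates evaluated on a shared grid spanning
#' both samples. 1 for identical distributions, 0 for disjoint ones.
#'
#' @param traceA,traceB `posterior_trace` objects (or data.frames).
#' @param parameter Column present in both.
#' @return Overlap in `[0, 1]`.
#' @export
posterior_overlap <- function(traceA, traceB, parameter) {
  a <- traceA[[parameter]]
  b <- traceB[[parameter]]
  if (is.null(a) || is.null(b)) stop("parameter missing from a trace")
  lo <- min(a, b); hi <- max(a, b)
  pad <- 0.1 * (hi - lo + 1e-12)
  grid <- seq(lo - pad, hi + pad, length.out = 1024)
  da <- stats::density(a, from = grid[1], to = grid[length(grid)], n = 1024)
  db <- stats::density(b, from = grid[1], to = grid[length(grid)], n = 1024)
  y <- pmin(da$y, db$y)
  sum((y[-1] + y[-length(y)]) / 2 * diff(da$x))
}

#' Posterior of the segment onset age
#'
#' Summary of `root_age`: the age (years since birth) of the last common
#' ancestor with an unaltered genome.
#'
#' @param trace A `posterior_trace` containing `root_age`.
#' @inheritParams summarize_posterior
#' @return As [summarize_posterior()].
#' @export
onset_age <- function(trace, prob = 0.95)
  summarize_posterior(trace, "root_age", prob)
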