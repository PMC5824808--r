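#' Copy-number matrix for clock inference
#'
#' Container for the data the copy-number clock acts on: per (sample, locus,
#' allele) an integer copy state in `0..K`, a sampling age in years for every
#' sample, and optionally a per-sample genome-doubling flag (an irreversible
#' binary character overlaid on the birth-death chain).
#'
#' @param states Integer array `[samples, loci, alleles=2]` with dimnames on
#'   the first margin; `NA` allowed (marginalised in the likelihood).
#' @param ages Named numeric vector of sampling ages (years since birth).
#' @param gd Optional named logical vector of genome-doubling flags.
#' @param K Maximum copy state (chain cap), default 4.
#' @return A `cn_matrix`.
#' @export
cn_matrix <- function(states, ages, gd = NULL, K = 4L) {
  stopifnot(length(dim(states)) == 3, dim(states)[3] == 2)
  ids <- dimnames(states)[[1]]
  if (is.null(ids)) stop("states needs sample ids as dimnames")
  if (!setequal(ids, names(ages))) stop("ages must be named by sample")
  if (any(ages <= 0)) stop("sampling ages must be positive")
  if (any(states < 0 | states > K, na.rm = TRUE))
    stop("states must lie in [0, K]")
  if (!is.null(gd) && !setequal(ids, names(gd)))
    stop("gd must be named by sample")
  structure(list(states = states, ages = ages[ids],
                 gd = if (is.null(gd)) NULL else gd[ids], K = as.integer(K)),
            class = "cn_matrix")
}

#' Build a CN matrix from segment profiles
#'
#' Each grid segment is one locus. Samples flagged as genome-doubled
#' (length-weighted ploidy above `gd_threshold`) have their per-allele states
#' halved toward the nearest integer before entry, and carry `gd = TRUE`;
#' the doubling itself is modelled as a separate binary character.
#'
#' @param profiles List of `segment_profile` (shared grid).
#' @param ages Named numeric sampling ages.
#' @param K Chain cap.
#' @param gd_threshold Ploidy threshold for the overlay GD call.
#' @return A `cn_matrix`.
#' @export
profiles_to_cn_matrix <- function(profiles, ages, K = 4L, gd_threshold = 3) {
  ids <- vapply(profiles, sample_id_of, "")
  n_loci <- nrow(profiles[[1]])
  states <- array(NA_integer_, c(length(ids), n_loci, 2),
                  dimnames = list(ids, NULL, NULL))
  gd <- logical(length(ids))
  names(gd) <- ids
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    cn1 <- p$cn1; cn2 <- p$cn2
    gd[i] <- call_gd(sample_ploidy(p), gd_threshold)
    if (gd[i]) {
      cn1 <- floor(cn1 / 2 + 0.5)
      cn2 <- floor(cn2 / 2 + 0.5)
    }
    states[i, , 1] <- pmin(cn1, K)
    states[i, , 2] <- pmin(cn2, K)
  }
  cn_matrix(states, ages, gd = gd, K = K)
}

#' Per-allele-copy birth-death generator
#'
#' Rate matrix of the copy-number chain on states `0..K`: each existing copy
#' of an allele gains at rate `rho * lambda` and is lost at rate
#' `(1 - rho) * lambda`, so `q(c -> c+1) = rho * lambda * c` (for `c < K`)
#' and `q(c -> c-1) = (1 - rho) * lambda * c`. State 0 (both copies of the
#' allele lost) is absorbing: loss of heterozygosity is irreversible.
#'
#' @param K Maximum state (>= 1).
#' @param lambda Events per allele copy per locus per year.
#' @param rho Fraction of events that are gains, in `[0, 1]`.
#' @return `(K+1) x (K+1)` generator with rows summing to zero.
#' @export
build_generator <- function(K, lambda, rho) {
  if (K < 1) stop("K must be >= 1")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  n <- K + 1L
  Q <- matrix(0, n, n)
  for (c in 1:K) {
    i <- c + 1L
    if (c < K) Q[i, i + 1L] <- rho * lambda * c
    Q[i, i - 1L] <- (1 - rho) * lambda * c
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Matrix exponential by uniformisation; robust for any generator.
expm_uniform <- function(Q, t) {
  n <- nrow(Q)
  m <- max(-diag(Q)) * t
  if (m == 0) return(diag(n))
  A <- Q * t / m + diag(n)
  term <- diag(n) * exp(-m)
  P <- term
  k <- 0
  repeat {
    k <- k + 1
    term <- (term %*% A) * (m / k)
    P <- P + term
    if (k > m + 40 * sqrt(m + 1) + 20) break
  }
  P
}

# Eigendecomposition of a generator, cached by callers; NULL if unusable.
generator_eigen <- function(Q) {
  e <- tryCatch(eigen(Q), error = function(e) NULL)
  if (is.null(e)) return(NULL)
  if (max(abs(Im(e$values))) > 1e-9) return(NULL)
  V <- Re(e$vectors)
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vinv)) return(NULL)
  if (max(abs(V %*% Vinv - diag(nrow(Q)))) > 1e-8) return(NULL)
  list(values = Re(e$values), V = V, Vinv = Vinv)
}

expm_eigen <- function(eg, t)
  eg$V %*% (exp(eg$values * t) * eg$Vinv)

#' Transition probabilities of the copy-number chain
#'
#' `exp(Q * t)` for a generator and an elapsed time (already multiplied by
#' any branch rate). Uses the eigendecomposition when well conditioned,
#' falling back to uniformisation.
#'
#' @param generator Square generator matrix (see [build_generator()]).
#' @param elapsed Non-negative elapsed time x rate.
#' @return Row-stochastic transition matrix.
#' @export
transition_probs <- function(generator, elapsed) {
  if (elapsed < 0) stop("elapsed time must be >= 0")
  eg <- generator_eigen(generator)
  P <- if (!is.null(eg)) expm_eigen(eg, elapsed)
       else expm_uniform(generator, elapsed)
  P[P < 0] <- 0
  P / rowSums(P)
}

# ---- internal tree representation for the clock ------------------------
# A clock tree is a list: tip_label (n), parent (2n-1 ints, 0 at root),
# age (years since birth; parents strictly older = smaller age), root index.
# Tips are 1..n, internals n+1..2n-1. Per-node rlc indicator/multiplier
# attach to the branch from the node to its parent.

clock_tree_children <- function(ct) {
  kids <- vector("list", length(ct$parent))
  for (v in seq_along(ct$parent)) {
    p <- ct$parent[v]
    if (p > 0) kids[[p]] <- c(kids[[p]], v)
  }
  kids
}

# order in which nodes can be processed children-first (ages strictly
# decrease toward the root, so descending age = postorder)
clock_tree_postorder <- function(ct) order(ct$age, decreasing = TRUE)

clock_tree_to_phylo <- function(ct, rates = NULL) {
  n <- length(ct$tip_label)
  old2new <- integer(length(ct$parent))
  old2new[seq_len(n)] <- seq_len(n)
  internals <- setdiff(seq_along(ct$parent), seq_len(n))
  internals <- c(ct$root, setdiff(internals, ct$root))
  old2new[internals] <- n + seq_along(internals)
  nonroot <- setdiff(seq_along(ct$parent), ct$root)
  edge <- cbind(old2new[ct$parent[nonroot]], old2new[nonroot])
  len <- ct$age[nonroot] - ct$age[ct$parent[nonroot]]
  ord <- order(edge[, 1], edge[, 2])
  tr <- structure(list(edge = edge[ord, , drop = FALSE],
                       tip.label = ct$tip_label,
                       edge.length = len[ord], Nnode = n - 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  if (!is.null(rates)) {
    ann <- list(rate = rep(NA_real_, 2L * n - 1L))
    ann$rate[old2new[nonroot]] <- rates[nonroot]
    attr(tr, "node_annotations") <- ann
  }
  tr
}

phylo_to_clock_tree <- function(tree, tip_ages) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
  depth <- numeric(n + tree$Nnode)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- tree$edge.length[match(paste(pre[, 1], pre[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]
  for (i in seq_len(nrow(pre)))
    depth[pre[i, 2]] <- depth[pre[i, 1]] + elen[i]
  root_age <- tip_ages[tree$tip.label[1]] - depth[1]
  age <- root_age + depth
  err <- max(abs(age[seq_len(n)] - tip_ages[tree$tip.label]))
  if (is.na(err) || err > 1e-6)
    stop("tree depths inconsistent with tip sampling ages")
  list(tip_label = tree$tip.label, parent = parent, age = age,
       root = n + 1L)
}

# effective per-branch multiplier under the random local clock: the product
# of active multipliers on the root-to-branch path (branch inclusive)
rlc_effective <- function(ct, indicators, multipliers) {
  eff <- rep(1, length(ct$parent))
  for (v in order(ct$age)) {           # preorder: parents first
    p <- ct$parent[v]
    if (p == 0) next
    eff[v] <- eff[p] * if (indicators[v] == 1) multipliers[v] else 1
  }
  eff
}

#' Phylogenetic log-likelihood of copy-number states
#'
#' Felsenstein pruning over loci x alleles under the per-allele-copy
#' birth-death chain. The unaltered ancestor sits at `state$root_age` with
#' state 1 on every allele of every locus; a stem branch connects it to the
#' most recent common ancestor of the samples. Branch rates are
#' `lambda` times the product of active random-local-clock multipliers on
#' the root-to-branch path. When the matrix carries genome-doubling flags,
#' an independent irreversible binary character with rate `state$gd_rate`
#' multiplies into the likelihood. `NA` tip states are marginalised.
#'
#' @param tree Rooted time-calibrated `phylo` (branch lengths in years) whose
#'   tip ages equal the sampling ages of `cn`.
#' @param cn A `cn_matrix`.
#' @param state List with `lambda`, `rho`, `root_age`, and optionally
#'   `gd_rate`, `rlc_indicators`, `rlc_multipliers` (per node, indexed as in
#'   the internal clock tree; defaults = strict clock).
#' @return Log-likelihood.
#' @export
tree_log_likelihood <- function(tree, cn, state) {
  ct <- phylo_to_clock_tree(tree, cn$ages)
  clock_log_likelihood(ct, cn, state)
}

# precompute the per-tip partial-likelihood matrices (constant per dataset)
cn_tip_partials <- function(cn, tip_labels) {
  K1 <- cn$K + 1L
  n_loci <- dim(cn$states)[2]
  lapply(tip_labels, function(s) {
    st <- c(cn$states[s, , 1], cn$states[s, , 2])
    L <- matrix(0, n_loci * 2L, K1)
    na <- is.na(st)
    if (any(na)) L[na, ] <- 1
    L[cbind(which(!na), st[!na] + 1L)] <- 1
    L
  })
}

clock_log_likelihood <- function(ct, cn, state, eg = NULL, tipL = NULL) {
  n <- length(ct$tip_label)
  K1 <- cn$K + 1L
  if (!setequal(ct$tip_label, dimnames(cn$states)[[1]]))
    stop("tree tips must match cn sample ids")
  if (state$lambda < 0 || state$rho < 0 || state$rho > 1)
    stop("invalid clock state")
  nv <- length(ct$parent)
  ind <- state$rlc_indicators %||% rep(0L, nv)
  mult <- state$rlc_multipliers %||% rep(1, nv)
  if (any(mult <= 0)) stop("rate multipliers must be positive")
  stem <- ct$age[ct$root] - state$root_age
  if (stem < 0) return(-Inf)
  if (is.null(eg)) eg <- generator_eigen(build_generator(cn$K, 1, state$rho))
  Q0 <- if (is.null(eg)) build_generator(cn$K, 1, state$rho) else NULL
  Pfun <- function(s) {
    if (!is.null(eg)) expm_eigen(eg, s) else expm_uniform(Q0, s)
  }
  eff <- rlc_effective(ct, ind, mult)
  n_char <- dim(cn$states)[2] * 2L
  ll <- 0
  if (n_char > 0) {
    if (is.null(tipL)) tipL <- cn_tip_partials(cn, ct$tip_label)
    partial <- vector("list", nv)
    logscale <- 0
    scale_ctr <- 0L
    for (v in clock_tree_postorder(ct)) {
      if (v <= n) partial[[v]] <- tipL[[v]]
      # internal nodes already hold the product of their children's messages
      p <- ct$parent[v]
      if (p > 0) {
        P <- Pfun(state$lambda * eff[v] * (ct$age[v] - ct$age[p]))
        msg <- tcrossprod(partial[[v]], P)
        if (is.null(partial[[p]])) {
          partial[[p]] <- msg
        } else {
          partial[[p]] <- partial[[p]] * msg
          scale_ctr <- scale_ctr + 1L
          if (scale_ctr %% 8L == 0L) {  # occasional rescale vs underflow
            mx <- rowSums(partial[[p]])
            mx[mx == 0] <- 1
            partial[[p]] <- partial[[p]] / mx
            logscale <- logscale + sum(log(mx))
          }
        }
      }
    }
    rootP <- Pfun(state$lambda * stem)
    lik <- as.vector(partial[[ct$root]] %*% rootP[2, ])
    if (any(lik <= 0)) return(-Inf)
    ll <- sum(log(lik)) + logscale
  }
  if (!is.null(cn$gd)) {
    g <- state$gd_rate %||% 0
    ll <- ll + gd_log_likelihood(ct, cn$gd, g, stem)
  }
  ll
}

gd_log_likelihood <- function(ct, gd, gd_rate, stem = 0) {
  n <- length(ct$tip_label)
  gdv <- as.integer(gd[ct$tip_label])
  partial <- vector("list", length(ct$parent))
  Pgd <- function(t) {
    e <- exp(-gd_rate * t)
    matrix(c(e, 0, 1 - e, 1), 2, 2)
  }
  logscale <- 0
  for (v in clock_tree_postorder(ct)) {
    L <- if (v <= n) {
      x <- c(0, 0)
      x[gdv[v] + 1L] <- 1
      x
    } else partial[[v]]
    p <- ct$parent[v]
    if (p > 0) {
      msg <- as.vector(Pgd(ct$age[v] - ct$age[p]) %*% L)
      partial[[p]] <- if (is.null(partial[[p]])) msg else partial[[p]] * msg
    } else partial[[v]] <- L
  }
  root <- partial[[ct$root]]
  # unaltered ancestor is undoubled; doubling may occur on the stem
  lik <- as.vector(Pgd(stem) %*% root)[1]
  if (lik <= 0) return(-Inf)
  log(lik)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Constant-size coalescent log prior
#'
#' Log density of a time-calibrated tree under the constant-size coalescent
#' with scale `Ne_tau` (years), supporting serially sampled
#' (heterochronous) tips.
#'
#' @param tree Rooted binary `phylo` with branch lengths in years.
#' @param Ne_tau Coalescent scale (effective size x generation time), years.
#' @return Log density.
#' @export
coalescent_log_prior <- function(tree, Ne_tau) {
  n <- length(tree$tip.label)
  ages <- numeric(n + tree$Nnode)   # time before present; root deepest
  pre <- ape::reorder.phylo(tree, "cladewise")
  depth <- numeric(n + tree$Nnode)
  for (i in seq_len(nrow(pre$edge)))
    depth[pre$edge[i, 2]] <- depth[pre$edge[i, 1]] + pre$edge.length[i]
  times <- max(depth) - depth
  coalescent_log_prior_times(times[seq_len(n)], times[-seq_len(n)], Ne_tau)
}

coalescent_log_prior_times <- function(tip_times, node_times, Ne_tau) {
  if (Ne_tau <= 0) stop("Ne_tau must be positive")
  t <- c(tip_times, node_times)
  type <- rep(c(1L, -1L), c(length(tip_times), length(node_times)))
  o <- order(t, -type)            # at ties, add lineages first
  t <- t[o]; type <- type[o]
  k <- cumsum(type)               # lineages after each event
  if (any(k[type == -1L] < 1L)) return(-Inf)
  kpre <- k - type                # lineages during the preceding interval
  dt <- diff(c(t[1], t))
  -sum(kpre * (kpre - 1) / 2 * dt) / Ne_tau -
    length(node_times) * log(Ne_tau)
}

#' Random-local-clock log prior
#'
#' A Poisson prior with mean `expected_changes` on the number of active
#' rate-change indicators, uniform over their placements on the branches,
#' and independent log-normal(0, `sigma`) priors on active multipliers;
#' inactive multipliers are fixed at 1.
#'
#' @param indicators 0/1 vector, one per non-root branch.
#' @param multipliers Positive multipliers, same length; entries with
#'   indicator 0 must equal 1.
#' @param expected_changes Prior mean number of rate changes (default ln 2,
#'   so the prior probability of at least one change is 1/2).
#' @param sigma Log-normal standard deviation.
#' @return Log density.
#' @export
rlc_log_prior <- function(indicators, multipliers,
                          expected_changes = log(2), sigma = 1) {
  if (length(indicators) != length(multipliers))
    stop("indicators and multipliers must align")
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  k <- sum(indicators == 1)
  B <- length(indicators)
  lp <- stats::dpois(k, expected_changes, log = TRUE) - lchoose(B, k)
  if (k > 0)
    lp <- lp + sum(stats::dlnorm(multipliers[indicators == 1], 0, sigma,
                                 log = TRUE))
  lp
}
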