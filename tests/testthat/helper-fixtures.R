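# Shared fixtures and independent oracles used across test files.

tiny_grid <- function() toy_genome_grid(n_chrom = 2, chrom_len = 10e6,
                                        locus_bp = 2e6)

# a hand-built profile on an arbitrary grid
profile_from_states <- function(grid, cn1, cn2, sample_id = "s1",
                                phased = TRUE) {
  seg <- grid_segments(grid)
  segment_profile(data.frame(chrom = seg$chrom, start = seg$start,
                             end = seg$end, cn1 = cn1, cn2 = cn2),
                  sample_id, phased = phased)
}

# independent marker counter: boundaries (incl. chromosome ends) where an
# allele state deviates; written without the package's extraction code
count_markers_independent <- function(profile) {
  n <- 0L
  for (ch in unique(profile$chrom)) {
    seg <- profile[profile$chrom == ch, ]
    for (a in 1:2) {
      cn <- c(1L, seg[[paste0("cn", a)]], 1L)
      n <- n + sum(cn[-1] != cn[-length(cn)])
    }
  }
  n
}

# exhaustive small-parsimony oracle: minimum changes of one binary character
# over all ancestral state assignments of a rooted nested-list tree
brute_min_changes <- function(tree_nested, states) {
  # tree_nested: nested list of tip names; states named 0/1/NA
  tips <- c()
  walk <- function(nd) if (is.character(nd)) tips <<- c(tips, nd) else
    lapply(nd, walk)
  walk(tree_nested)
  n_int <- length(tips) - 1L
  best <- Inf
  grid <- expand.grid(rep(list(0:1), n_int))
  for (g in seq_len(nrow(grid))) {
    asn <- as.integer(grid[g, ])
    idx <- 0L
    cost <- function(nd) {
      # returns list(state, changes)
      if (is.character(nd)) {
        s <- states[[nd]]
        return(list(state = s, changes = 0L, wild = is.na(s)))
      }
      idx <<- idx + 1L
      me <- asn[idx]
      ch <- lapply(nd, cost)
      changes <- sum(vapply(ch, `[[`, 0L, "changes"))
      for (c1 in ch) {
        if (isTRUE(c1$wild)) next
        if (c1$state != me) changes <- changes + 1L
      }
      list(state = me, changes = changes, wild = FALSE)
    }
    best <- min(best, cost(tree_nested)$changes)
  }
  best
}

# brute-force tree likelihood by enumerating internal node states
brute_tree_loglik <- function(ct, cn, state) {
  K <- cn$K
  n <- length(ct$tip_label)
  Q <- build_generator(K, state$lambda, state$rho)
  Pt <- function(t) transition_probs(Q, t)
  stem <- ct$age[ct$root] - state$root_age
  nodes_int <- setdiff(seq_along(ct$parent), seq_len(n))
  n_char <- dim(cn$states)[2] * 2L
  tips <- cbind(cn$states[ct$tip_label, , 1], cn$states[ct$tip_label, , 2])
  tot <- 0
  combos <- expand.grid(rep(list(0:K), length(nodes_int)))
  for (chx in seq_len(n_char)) {
    s <- 0
    for (g in seq_len(nrow(combos))) {
      asn <- as.integer(combos[g, ])
      names(asn) <- nodes_int
      pr <- Pt(stem)[2, asn[as.character(ct$root)] + 1]
      for (v in seq_along(ct$parent)) {
        p <- ct$parent[v]
        if (p == 0) next
        sv <- if (v <= n) tips[v, chx] else asn[as.character(v)]
        if (is.na(sv)) next   # handled by marginalisation below
        pv <- asn[as.character(p)]
        pr <- pr * Pt(ct$age[v] - ct$age[p])[pv + 1, sv + 1]
      }
      s <- s + pr
    }
    tot <- tot + log(s)
  }
  tot
}

# rejection sampler from the joint prior of the clock model (tree, ages)
draw_joint_prior <- function(ages, lambda_range = c(1e-5, 1),
                             ne_range = c(0.1, 1000), span = 60) {
  lo <- min(ages) - span
  repeat {
    ne <- exp(stats::runif(1, log(ne_range[1]), log(ne_range[2])))
    ct <- sim_coalescent_tree(ages, ne)
    if (ct$age[ct$root] <= max(lo, 0)) next
    ra <- stats::runif(1, lo, min(ages))
    if (ra > 0 && ra < ct$age[ct$root])
      return(list(lambda = exp(stats::runif(1, log(lambda_range[1]),
                                            log(lambda_range[2]))),
                  rho = stats::runif(1), Ne_tau = ne, root_age = ra,
                  ct = ct))
  }
}
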