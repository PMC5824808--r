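#' Simulate a constant-size coalescent tree with serial tips
#'
#' Backward-in-time simulation of the constant-size coalescent with scale
#' `Ne_tau` for tips sampled at given ages (years since birth).
#'
#' @param tip_ages Named numeric vector of tip sampling ages.
#' @param Ne_tau Coalescent scale in years.
#' @return An internal clock tree (tip labels, parent pointers, node ages);
#'   convert with [clock_tree_as_phylo()].
#' @export
sim_coalescent_tree <- function(tip_ages, Ne_tau) {
  n <- length(tip_ages)
  stopifnot(n >= 2, !is.null(names(tip_ages)))
  a_max <- max(tip_ages)
  tau <- a_max - tip_ages        # time before the latest tip
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  age <- c(tip_ages, numeric(n - 1L))
  pending <- order(tau)          # tips not yet entered
  active <- integer(0)
  t_cur <- 0
  next_int <- n + 1L
  repeat {
    t_entry <- if (length(pending)) tau[pending[1]] else Inf
    k <- length(active)
    t_coal <- if (k >= 2) t_cur + stats::rexp(1, k * (k - 1) / 2 / Ne_tau)
              else Inf
    if (t_entry <= t_coal) {
      if (!is.finite(t_entry)) break
      t_cur <- t_entry
      active <- c(active, pending[1])
      pending <- pending[-1]
    } else {
      pick <- sample(seq_along(active), 2)
      v <- next_int
      parent[active[pick]] <- v
      age[v] <- a_max - t_coal
      active <- c(active[-pick], v)
      t_cur <- t_coal
      next_int <- next_int + 1L
    }
    if (!length(pending) && length(active) == 1L) break
  }
  list(tip_label = names(tip_ages), parent = parent, age = age,
       root = n_nodes)
}

#' Convert an internal clock tree to `phylo`
#'
#' @param ct Internal clock tree (see [sim_coalescent_tree()]).
#' @param rates Optional per-node branch rates stored as a `rate` annotation.
#' @return Rooted `phylo` with branch lengths in years.
#' @export
clock_tree_as_phylo <- function(ct, rates = NULL)
  clock_tree_to_phylo(ct, rates)

#' Simulate copy-number tip states on a clock tree
#'
#' Exact (Gillespie) simulation of the per-allele-copy birth-death chain
#' along every branch, independently for each locus x allele, starting from
#' state 1 per allele at the unaltered ancestor (`root_age`), with optional
#' per-node branch-rate multipliers (random local clock truth).
#'
#' @param ct Internal clock tree.
#' @param n_loci Number of loci.
#' @param lambda Events per allele copy per locus per year.
#' @param rho Gain fraction.
#' @param K Chain cap.
#' @param root_age Age of the unaltered ancestor (must predate the tree
#'   root).
#' @param branch_mult Optional per-node effective rate multipliers
#'   (default 1).
#' @return A `cn_matrix` (no genome-doubling flags).
#' @export
sim_cn_on_tree <- function(ct, n_loci, lambda, rho, K = 4L, root_age,
                           branch_mult = NULL) {
  n <- length(ct$tip_label)
  nv <- length(ct$parent)
  if (is.null(branch_mult)) branch_mult <- rep(1, nv)
  stem <- ct$age[ct$root] - root_age
  if (stem < 0) stop("root_age must predate the tree root")
  n_char <- n_loci * 2L
  states <- matrix(NA_integer_, nv, n_char)
  states[ct$root, ] <- vapply(seq_len(n_char), function(j)
    evolve_chain_state(1L, lambda * stem, rho, K), 0L)
  for (v in rev(clock_tree_postorder(ct))) {   # preorder: parents first
    p <- ct$parent[v]
    if (p == 0) next
    s <- lambda * branch_mult[v] * (ct$age[v] - ct$age[p])
    states[v, ] <- vapply(seq_len(n_char), function(j)
      evolve_chain_state(states[p, j], s, rho, K), 0L)
  }
  arr <- array(NA_integer_, c(n, n_loci, 2),
               dimnames = list(ct$tip_label, NULL, NULL))
  arr[, , 1] <- states[seq_len(n), seq_len(n_loci)]
  arr[, , 2] <- states[seq_len(n), n_loci + seq_len(n_loci)]
  ages <- ct$age[seq_len(n)]
  names(ages) <- ct$tip_label
  cn_matrix(arr, ages, K = K)
}

# evolve one chain state for scaled time s (= lambda * t), exact Gillespie
evolve_chain_state <- function(state, s, rho, K) {
  t <- 0
  repeat {
    if (state == 0L) return(0L)
    up <- if (state < K) rho * state else 0
    down <- (1 - rho) * state
    tot <- up + down
    if (tot == 0) return(state)
    t <- t + stats::rexp(1, tot)
    if (t > s) return(state)
    state <- if (stats::runif(1) < up / tot) state + 1L else state - 1L
  }
}

#' Monte-Carlo simulation of the copy-number chain
#'
#' Simulates many independent paths of the per-allele-copy birth-death chain
#' for a fixed scaled time, vectorised over paths. Serves as a
#' simulation-based check of [transition_probs()].
#'
#' @param n_paths Number of paths.
#' @param start Starting state.
#' @param lambda,rho,K Chain parameters.
#' @param t Elapsed time.
#' @return Integer vector of end states.
#' @export
simulate_chain_paths <- function(n_paths, start, lambda, rho, K, t) {
  state <- rep.int(as.integer(start), n_paths)
  clock <- numeric(n_paths)
  active <- rep(TRUE, n_paths)
  while (any(active)) {
    i <- which(active)
    st <- state[i]
    up <- ifelse(st < K, rho * lambda * st, 0)
    down <- (1 - rho) * lambda * st
    tot <- up + down
    dead <- tot == 0
    if (any(dead)) {
      active[i[dead]] <- FALSE
      i <- i[!dead]
      if (!length(i)) break
      st <- state[i]; up <- up[!dead]; tot <- tot[!dead]
    }
    clock[i] <- clock[i] + stats::rexp(length(i), tot)
    done <- clock[i] > t
    active[i[done]] <- FALSE
    j <- i[!done]
    if (length(j)) {
      jump_up <- stats::runif(length(j)) < (up[!done] / tot[!done])
      state[j] <- state[j] + ifelse(jump_up, 1L, -1L)
    }
  }
  state
}
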