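#' Consensus tree with branch rates and rate-change posteriors
#'
#' Builds the majority-rule consensus of the sampled trees of a
#' [mcmc_run()] fit and annotates every consensus branch with the posterior
#' mean effective SCA rate (averaged over the samples containing the clade),
#' the clade's posterior probability, and — under the random local clock —
#' the posterior probability of a rate change on the clade's stem branch
#' conditional on the clade (the style of presentation used for
#' mutator-clone analyses).
#'
#' @param fit A `clock_fit` with at least 100 retained trees.
#' @return List: `tree` (consensus `phylo`, node annotations `rate` and
#'   `posterior`), `rate_changes` (data.frame of clades with conditional
#'   rate-change posteriors and mean rates).
#' @export
annotate_rate_changes <- function(fit) {
  trees <- fit$trees
  if (length(trees) < 100) stop("need >= 100 sampled trees")
  tips <- sort(trees[[1]]$ct$tip_label)
  n <- length(tips)
  stat <- new.env(parent = emptyenv())
  for (s in trees) {
    ct <- s$ct
    tipidx <- match(ct$tip_label, tips)
    nv <- length(ct$parent)
    below <- vector("list", nv)
    for (v in clock_tree_postorder(ct)) {
      if (v <= n) below[[v]] <- tipidx[v]
      p <- ct$parent[v]
      if (p > 0) below[[p]] <- c(below[[p]], below[[v]])
    }
    for (v in seq_len(nv)) {
      key <- paste(sort(below[[v]]), collapse = ",")
      e <- stat[[key]]
      if (is.null(e)) e <- list(count = 0, rate = 0, age = 0, ind = 0)
      e$count <- e$count + 1
      if (v != ct$root) {
        e$rate <- e$rate + s$eff_rate[v]
        e$ind <- e$ind + s$ind[v]
      }
      e$age <- e$age + ct$age[v]
      stat[[key]] <- e
    }
  }
  n_samp <- length(trees)
  keys <- ls(stat)
  freq <- vapply(keys, function(k) stat[[k]]$count / n_samp, 0)
  keep <- keys[freq > 0.5 | vapply(keys, function(k)
    !grepl(",", k), TRUE)]
  root_key <- paste(seq_len(n), collapse = ",")
  if (!root_key %in% keep) keep <- c(keep, root_key)
  sizes <- vapply(strsplit(keep, ","), length, 0L)
  ord <- order(-sizes)
  keep <- keep[ord]; sizes <- sizes[ord]
  sets <- lapply(strsplit(keep, ","), as.integer)
  # parent of each clade = smallest kept strict superset
  parent_key <- vapply(seq_along(keep), function(i) {
    if (keep[i] == root_key) return(NA_character_)
    sup <- which(sizes > sizes[i] &
                 vapply(sets, function(s) all(sets[[i]] %in% s), TRUE))
    cand <- sup[which.min(sizes[sup])]
    keep[cand]
  }, "")
  # phylo numbering: tips 1..n (sorted labels), internals by decreasing size
  is_tip <- sizes == 1L
  node_num <- integer(length(keep))
  node_num[is_tip] <- vapply(sets[is_tip], identity, 0L)
  node_num[!is_tip] <- n + seq_len(sum(!is_tip))
  edge <- cbind(node_num[match(parent_key, keep)], node_num)
  ok <- !is.na(edge[, 1])
  ages <- vapply(keep, function(k) stat[[k]]$age / stat[[k]]$count, 0)
  elen <- pmax(0, ages - ages[match(parent_key, keep)])
  tr <- structure(list(edge = edge[ok, , drop = FALSE], tip.label = tips,
                       edge.length = elen[ok],
                       Nnode = sum(!is_tip)),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  ann <- list(rate = rep(NA_real_, n + tr$Nnode),
              posterior = rep(NA_real_, n + tr$Nnode))
  for (i in seq_along(keep)) {
    e <- stat[[keep[i]]]
    ann$rate[node_num[i]] <- e$rate / e$count
    ann$posterior[node_num[i]] <- e$count / n_samp
  }
  attr(tr, "node_annotations") <- ann
  rate_changes <- data.frame(
    clade = keep,
    n_tips = sizes,
    posterior = freq[match(keep, keys)],
    mean_rate = vapply(keep, function(k)
      stat[[k]]$rate / stat[[k]]$count, 0),
    p_rate_change = vapply(keep, function(k)
      stat[[k]]$ind / stat[[k]]$count, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  list(tree = tr, rate_changes = rate_changes)
}

#' Posterior probability of a rate shift affecting a clade
#'
#' The probability, over retained samples in which the given tips form a
#' monophyletic clade, that at least one random-local-clock indicator is
#' active on the path from the root to the clade's stem branch (stem
#' inclusive) or, optionally, within the clade. Samples in which the tips
#' are not monophyletic count as no shift.
#'
#' @param fit A `clock_fit` run in `rlc` mode.
#' @param clade_tips Character vector of tip labels.
#' @param within Also count indicators on branches inside the clade.
#' @return Probability in `[0, 1]`.
#' @export
rate_shift_posterior <- function(fit, clade_tips, within = TRUE) {
  hits <- vapply(fit$trees, function(s) {
    ct <- s$ct
    n <- length(ct$tip_label)
    idx <- match(clade_tips, ct$tip_label)
    if (anyNA(idx)) return(0)
    # MRCA of the clade tips
    anc <- function(v) {
      out <- integer(0)
      while (v != 0) { out <- c(out, v); v <- ct$parent[v] }
      out
    }
    paths <- lapply(idx, anc)
    common <- Reduce(intersect, paths)
    mrca <- common[1]
    # descendant tips of mrca
    desc <- function(v) {
      kids <- which(ct$parent == v)
      if (!length(kids)) return(v)
      unlist(lapply(kids, desc))
    }
    tips_below <- desc(mrca)
    tips_below <- tips_below[tips_below <= n]
    if (!setequal(tips_below, idx)) return(0)
    on_path <- anc(mrca)
    on_path <- setdiff(on_path, ct$root)
    extra <- if (within) {
      inside <- setdiff(unlist(lapply(which(ct$parent == mrca), function(k) {
        vs <- k
        out <- integer(0)
        stack <- k
        while (length(stack)) {
          v <- stack[1]; stack <- stack[-1]
          out <- c(out, v)
          stack <- c(stack, which(ct$parent == v))
        }
        out
      })), integer(0))
      inside
    } else integer(0)
    as.numeric(any(s$ind[c(on_path, extra)] == 1))
  }, 0)
  mean(hits)
}
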