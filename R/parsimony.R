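#' Maximum-parsimony inference from breakpoint presence/absence
#'
#' Characters are binary (marker present/absent); `NA` is a wildcard that may
#' take either state. Trees are rooted by an explicit all-absent "normal"
#' pseudo-tip representing the unaltered ancestral genome; the pseudo-tip is
#' excluded from diversity statistics.
#'
#' Internally trees are nested lists (a tip is its label, an internal node a
#' list of two children); the exported surface converts to `ape::phylo`.
#'
#' @name parsimony
NULL

NORMAL_TIP <- "normal"

# ---- character encoding: state sets as bit masks (1 = absent, 2 = present) --
encode_states <- function(matrix) {
  enc <- matrix(3L, nrow(matrix), ncol(matrix),
                dimnames = dimnames(matrix))
  enc[which(matrix == 0)] <- 1L
  enc[which(matrix == 1)] <- 2L
  enc
}

# Fitch bottom-up pass on a nested-list tree. Returns list(set, changes).
fitch_rec <- function(node, enc) {
  if (is.character(node)) {
    if (!node %in% rownames(enc)) stop("tip '", node, "' not in matrix")
    return(list(set = enc[node, ], changes = 0L))
  }
  l <- fitch_rec(node[[1]], enc)
  r <- fitch_rec(node[[2]], enc)
  inter <- bitwAnd(l$set, r$set)
  disjoint <- inter == 0L
  set <- ifelse(disjoint, bitwOr(l$set, r$set), inter)
  list(set = set, changes = l$changes + r$changes + sum(disjoint))
}

fitch_score_nested <- function(tree, enc) fitch_rec(tree, enc)$changes

# ---- nested <-> phylo conversion ----
phylo_to_nested <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  rec <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    ch <- kids[[node]]
    if (length(ch) != 2) stop("tree must be binary and rooted")
    list(rec(ch[1]), rec(ch[2]))
  }
  rec(n_tip + 1L)
}

nested_to_phylo <- function(nested) {
  tips <- character(0)
  walk <- function(nd) {
    if (is.character(nd)) tips <<- c(tips, nd)
    else { walk(nd[[1]]); walk(nd[[2]]) }
  }
  walk(nested)
  n_tip <- length(tips)
  n_int <- n_tip - 1L
  edge <- matrix(0L, 2L * n_tip - 2L, 2L)
  tip_i <- 0L; int_i <- 1L; edge_i <- 0L
  # numbers assigned on entry so edges come out in true cladewise order
  rec <- function(nd, me) {
    for (child in nd) {
      if (is.character(child)) {
        tip_i <<- tip_i + 1L
        cn <- tip_i
      } else {
        int_i <<- int_i + 1L
        cn <- n_tip + int_i
      }
      edge_i <<- edge_i + 1L
      edge[edge_i, ] <<- c(me, cn)
      if (!is.character(child)) rec(child, cn)
    }
  }
  rec(nested, n_tip + 1L)
  structure(list(edge = edge, tip.label = tips, Nnode = n_int),
            class = "phylo", order = "cladewise")
}

canonical_newick <- function(node) {
  if (is.character(node)) return(node)
  parts <- sort(c(canonical_newick(node[[1]]), canonical_newick(node[[2]])))
  paste0("(", parts[1], ",", parts[2], ")")
}

#' Fitch parsimony score
#'
#' Minimum number of character changes of a binary character matrix on a
#' fixed rooted tree (Fitch bottom-up pass; `NA` entries are wildcards).
#'
#' @param tree Rooted binary `phylo`; every tip must be a row of `matrix`
#'   (the `"normal"` pseudo-tip is given an all-absent row automatically).
#' @param matrix Samples x characters 0/1/NA matrix.
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, matrix) {
  matrix <- add_normal_row(tree$tip.label, matrix)
  missing_tips <- setdiff(tree$tip.label, rownames(matrix))
  if (length(missing_tips))
    stop("tips not in matrix: ", paste(missing_tips, collapse = ","))
  fitch_score_nested(phylo_to_nested(tree), encode_states(matrix))
}

add_normal_row <- function(tips, matrix) {
  if (NORMAL_TIP %in% tips && !(NORMAL_TIP %in% rownames(matrix))) {
    matrix <- rbind(matrix, 0L)
    rownames(matrix)[nrow(matrix)] <- NORMAL_TIP
  }
  matrix
}

# ---- tree edit helpers on nested lists ----

# All trees obtained by inserting `tip` on each edge of `nested`, plus above
# the root (the root edge leads to the normal outgroup).
insertions <- function(nested, tip) {
  out <- list(list(nested, tip))
  rec <- function(nd, path) {
    # returns list of modified copies of nd with tip inserted somewhere inside
    res <- list()
    if (is.list(nd)) {
      for (k in 1:2) {
        child <- nd[[k]]
        repl <- nd
        repl[[k]] <- list(child, tip)   # insert on edge to child
        res <- c(res, list(repl))
        for (sub in rec(child, path)) { # insert deeper
          repl2 <- nd
          repl2[[k]] <- sub
          res <- c(res, list(repl2))
        }
      }
    }
    res
  }
  c(out, rec(nested, NULL))
}

# Nearest-neighbour-interchange neighbours of a nested tree (the tree is the
# ingroup clade; the outgroup/normal sits above its root).
nni_neighbours <- function(nested) {
  res <- list()
  rec <- function(nd, assemble) {
    if (!is.list(nd)) return()
    for (k in 1:2) {
      child <- nd[[k]]
      sib <- nd[[3 - k]]
      if (is.list(child)) {
        # edge nd -> child is internal: swap sib with either grandchild
        for (g in 1:2) {
          new_child <- child
          new_child[[g]] <- sib
          new_nd <- if (k == 1L) list(new_child, child[[g]])
                    else list(child[[g]], new_child)
          res[[length(res) + 1L]] <<- assemble(new_nd)
        }
      }
      rec(child, function(x) {
        new_nd <- nd
        new_nd[[k]] <- x
        assemble(new_nd)
      })
    }
  }
  rec(nested, function(x) x)
  res
}

enumerate_topologies <- function(tips) {
  # all unrooted topologies, represented rooted on the first tip's edge:
  # nested trees over tips[-1], the implicit outgroup being tips[1]
  stopifnot(length(tips) >= 3)
  start <- if (length(tips) == 2L) tips[2] else list(tips[2], tips[3])
  trees <- list(start)
  if (length(tips) > 3) {
    for (tp in tips[-(1:3)]) {
      trees <- do.call(c, lapply(trees, insertions, tip = tp))
    }
  }
  trees
}

#' Maximum-parsimony tree search
#'
#' Finds a minimum Fitch-score tree for a presence/absence character matrix,
#' rooted by an all-absent `"normal"` pseudo-tip. `mode = "exhaustive"`
#' enumerates every unrooted topology (allowed up to 9 samples);
#' `mode = "heuristic"` runs `n_restarts` rounds of random stepwise addition
#' followed by nearest-neighbour-interchange hill climbing. Co-optimal
#' topologies found along the way are recorded; ties are broken by the
#' lexicographically smallest canonical Newick string, making the result
#' deterministic given the seed.
#'
#' @param matrix Samples x characters 0/1/NA matrix (>= 3 samples).
#' @param mode `"exhaustive"` or `"heuristic"`.
#' @param n_restarts Restarts for the heuristic search.
#' @param seed Integer seed for the stepwise-addition orders.
#' @return List: `tree` (rooted `phylo` with the `"normal"` tip), `score`,
#'   `co_optimal` (canonical strings of distinct optimal ingroup
#'   topologies), `n_co_optimal`.
#' @export
search_parsimony <- function(matrix, mode = c("heuristic", "exhaustive"),
                             n_restarts = 20L, seed = 1L) {
  mode <- match.arg(mode)
  ids <- rownames(matrix)
  if (length(ids) < 3) stop("need >= 3 samples")
  full <- add_normal_row(c(NORMAL_TIP, ids), matrix)
  enc <- encode_states(full)
  best <- NULL
  best_score <- Inf
  co <- character(0)
  consider <- function(nested, score) {
    if (score < best_score) {
      best_score <<- score
      co <<- canonical_newick(nested)
      best <<- nested
    } else if (score == best_score) {
      key <- canonical_newick(nested)
      if (!key %in% co) {
        co <<- c(co, key)
        if (key == min(co)) best <<- nested
      }
    }
  }
  # score always includes the all-absent normal pseudo-tip above the
  # ingroup root: the tree is rooted in an unaltered ancestor
  rooted_score <- function(tr) fitch_score_nested(list(NORMAL_TIP, tr), enc)
  if (mode == "exhaustive") {
    if (length(ids) > 9) stop("exhaustive search limited to 9 samples")
    for (tr in enumerate_topologies(c(NORMAL_TIP, ids)))
      consider(tr, rooted_score(tr))
  } else {
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      ord <- sample(ids)
      cur <- if (length(ord) >= 2) list(ord[1], ord[2]) else ord[1]
      for (tp in ord[-(1:2)]) {
        cands <- insertions(cur, tp)
        scores <- vapply(cands, rooted_score, 0L)
        cur <- cands[[which.min(scores)]]
      }
      cur_score <- rooted_score(cur)
      repeat {
        nbs <- nni_neighbours(cur)
        if (!length(nbs)) break
        scores <- vapply(nbs, rooted_score, 0L)
        if (min(scores) < cur_score) {
          cur <- nbs[[which.min(scores)]]
          cur_score <- min(scores)
        } else break
      }
      consider(cur, cur_score)
    }
  }
  # rebuild the best (lexicographically smallest canonical) nested tree
  tree <- nested_to_phylo(list(NORMAL_TIP, best))
  list(tree = tree, score = as.integer(best_score), co_optimal = sort(co),
       n_co_optimal = length(co))
}

#' Assign per-branch change counts
#'
#' Minimum-change ancestral reconstruction (Sankoff dynamic programme with
#' unit costs) with ACCTRAN (default) or DELTRAN resolution of ambiguous
#' placements: ties in the backtrack prefer a change on the earlier
#' (rootward) branch under ACCTRAN and the later branch under DELTRAN. The
#' branch lengths always sum to the Fitch score.
#'
#' @param tree Rooted binary `phylo`.
#' @param matrix Samples x characters 0/1/NA matrix.
#' @param resolve `"acctran"` or `"deltran"`.
#' @return `phylo` with `edge.length` = number of changes per branch.
#' @export
assign_branch_lengths <- function(tree, matrix, resolve = c("acctran", "deltran")) {
  resolve <- match.arg(resolve)
  matrix <- add_normal_row(tree$tip.label, matrix)
  n_tip <- length(tree$tip.label)
  n_char <- ncol(matrix)
  n_node <- n_tip + tree$Nnode
  big <- 1e9
  # cost[state+1][[node]] = vector over chars of min subtree cost
  c0 <- matrix(0, n_node, n_char)
  c1 <- matrix(0, n_node, n_char)
  for (i in seq_len(n_tip)) {
    v <- matrix[tree$tip.label[i], ]
    c0[i, ] <- ifelse(is.na(v) | v == 0, 0, big)
    c1[i, ] <- ifelse(is.na(v) | v == 1, 0, big)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    # child's contribution to parent in each parent state
    add0 <- pmin(c0[ch, ], c1[ch, ] + 1)
    add1 <- pmin(c1[ch, ], c0[ch, ] + 1)
    c0[p, ] <- c0[p, ] + add0
    c1[p, ] <- c1[p, ] + add1
  }
  root <- n_tip + 1L
  # root state: minimal cost, ties resolved to the absent state (the tree
  # descends from an unaltered ancestor)
  state <- matrix(NA_integer_, n_node, n_char)
  state[root, ] <- ifelse(c1[root, ] < c0[root, ], 1L, 0L)
  pre <- rev(seq_len(nrow(po$edge)))
  changes <- numeric(nrow(tree$edge))
  edge_key <- paste(po$edge[, 1], po$edge[, 2])
  for (e in pre) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    ps <- state[p, ]
    stay <- ifelse(ps == 0, c0[ch, ], c1[ch, ])
    move <- ifelse(ps == 0, c1[ch, ], c0[ch, ]) + 1
    cs <- ifelse(move < stay, 1L - ps,
          ifelse(stay < move, ps,
                 if (resolve == "acctran") 1L - ps else ps))
    state[ch, ] <- cs
    changes[e] <- sum(cs != ps)
  }
  # map change counts from postorder edge order back to tree's edge order
  out <- tree
  key_tree <- paste(tree$edge[, 1], tree$edge[, 2])
  out$edge.length <- changes[match(key_tree, edge_key)]
  out
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths along the tree path connecting two samples.
#'
#' @param tree `phylo` with branch lengths.
#' @param sample1,sample2 Tip labels.
#' @return Numeric distance.
#' @export
patristic_distance <- function(tree, sample1, sample2) {
  i <- match(c(sample1, sample2), tree$tip.label)
  if (anyNA(i))
    stop("unknown tip: ",
         paste(c(sample1, sample2)[is.na(i)], collapse = ","))
  if (i[1] == i[2]) return(0)
  ape::dist.nodes(tree)[i[1], i[2]]
}

#' Distance from the unaltered ancestor
#'
#' Patristic distance between a sample and the `"normal"` pseudo-tip, i.e.
#' the inferred number of events separating the sample from an unaltered
#' genome.
#'
#' @inheritParams patristic_distance
#' @param sample Tip label.
#' @export
distance_from_normal <- function(tree, sample)
  patristic_distance(tree, sample, NORMAL_TIP)

#' All pairwise patristic distances
#'
#' @param tree `phylo` with branch lengths.
#' @return Symmetric matrix over tips.
#' @export
patristic_matrix <- function(tree) {
  d <- ape::dist.nodes(tree)[seq_along(tree$tip.label),
                             seq_along(tree$tip.label)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Evolutionary diversity of a group of samples
#'
#' Mean pairwise patristic distance over the unordered pairs of a group.
#'
#' @param tree `phylo` with branch lengths.
#' @param group Character vector of >= 2 tip labels.
#' @return Numeric mean pairwise distance.
#' @export
diversity <- function(tree, group) {
  group <- unique(group)
  if (length(group) < 2) stop("diversity needs at least two samples")
  d <- patristic_matrix(tree)[group, group]
  mean(d[upper.tri(d)])
}
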