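#' Annotated Newick tree I/O
#'
#' Trees are `ape::phylo` objects, always rooted, optionally carrying numeric
#' per-node annotations (e.g. `rate`, `posterior`) in the attribute
#' `node_annotations`: a named list of numeric vectors of length
#' `Ntip + Nnode`, indexed by ape node number, `NA` where a node is
#' unannotated. On disk they are Newick strings in which a node may carry a
#' BEAST-style comment `[&key=value,...]` between its label and its branch
#' length. `read_tree(write_tree(x))` is the identity on topology, branch
#' lengths and annotations.
#'
#' @param tree Rooted `phylo`, optionally with `node_annotations`.
#' @param path File path.
#' @return `write_tree` invisibly returns `path`; `read_tree` returns a
#'   rooted `phylo` with a `node_annotations` attribute.
#' @name tree_io
NULL

tree_annotations <- function(tree) {
  ann <- attr(tree, "node_annotations")
  if (is.null(ann)) ann <- list()
  ann
}

fmt_num <- function(x) sprintf("%.12g", x)

#' @rdname tree_io
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  n_tip <- length(tree$tip.label)
  ann <- tree_annotations(tree)
  kids <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  elen <- function(node) {
    i <- match(node, tree$edge[, 2])
    if (is.na(i) || is.null(tree$edge.length)) NA_real_
    else tree$edge.length[i]
  }
  annot_str <- function(node) {
    vals <- vapply(ann, function(v) v[node], 0)
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return("")
    paste0("[&", paste(names(vals), fmt_num(vals), sep = "=", collapse = ","),
           "]")
  }
  rec <- function(node) {
    lab <- if (node <= n_tip) tree$tip.label[node]
           else if (!is.null(tree$node.label)) tree$node.label[node - n_tip]
           else ""
    if (is.na(lab)) lab <- ""
    core <- if (node <= n_tip) lab
            else paste0("(", paste(vapply(kids[[node]], rec, ""),
                                   collapse = ","), ")", lab)
    len <- elen(node)
    paste0(core, annot_str(node),
           if (!is.na(len)) paste0(":", fmt_num(len)) else "")
  }
  writeLines(paste0(rec(n_tip + 1L), ";"), path)
  invisible(path)
}

#' @rdname tree_io
#' @export
read_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("[[:space:]]", "", txt)
  pos <- 1L
  n <- nchar(txt)
  perr <- function(msg) stop(sprintf("Newick parse error at position %d: %s",
                                     pos, msg), call. = FALSE)
  peek <- function() if (pos <= n) substr(txt, pos, pos) else ""
  scan_until <- function(stops) {
    start <- pos
    while (pos <= n && !(substr(txt, pos, pos) %in% stops)) pos <<- pos + 1L
    substr(txt, start, pos - 1L)
  }
  parse_annot <- function() {
    if (peek() != "[") return(list())
    pos <<- pos + 1L
    if (peek() != "&") perr("expected '&' in annotation")
    pos <<- pos + 1L
    body <- scan_until("]")
    if (peek() != "]") perr("unterminated annotation")
    pos <<- pos + 1L
    kv <- strsplit(body, ",", fixed = TRUE)[[1]]
    out <- list()
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2) perr("malformed key=value annotation")
      out[[parts[1]]] <- as.numeric(parts[2])
    }
    out
  }
  parse_node <- function() {
    node <- list(children = list(), label = "", length = NA_real_,
                 annot = list())
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        node$children <- c(node$children, list(parse_node()))
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        perr("expected ',' or ')'")
      }
    }
    node$label <- scan_until(c(":", ",", ")", ";", "["))
    node$annot <- parse_annot()
    if (peek() == ":") {
      pos <<- pos + 1L
      num <- scan_until(c(",", ")", ";", "["))
      node$length <- suppressWarnings(as.numeric(num))
      if (is.na(node$length)) perr("bad branch length")
    }
    node
  }
  root <- parse_node()
  if (peek() != ";") perr("expected ';'")
  if (!length(root$children)) perr("single leaf is not a tree")
  if (length(root$children) > 2)
    stop("tree is unrooted (root has more than two children)", call. = FALSE)
  build_phylo_from_nested(root)
}

# Convert the parser's nested-list form into phylo + node_annotations.
build_phylo_from_nested <- function(root) {
  tips <- character(0)
  walk_tips <- function(nd) {
    if (!length(nd$children)) tips <<- c(tips, nd$label)
    else for (ch in nd$children) walk_tips(ch)
  }
  walk_tips(root)
  n_tip <- length(tips)
  n_node_total <- 0L
  count_nodes <- function(nd) {
    n_node_total <<- n_node_total + 1L
    for (ch in nd$children) count_nodes(ch)
  }
  count_nodes(root)
  n_int <- n_node_total - n_tip
  edge <- matrix(0L, n_node_total - 1L, 2)
  edge_len <- rep(NA_real_, n_node_total - 1L)
  node_label <- character(n_int)
  ann <- list()
  tip_i <- 0L; int_i <- 0L; edge_i <- 0L
  set_ann <- function(num, annot) {
    for (k in names(annot)) {
      if (is.null(ann[[k]])) ann[[k]] <<- rep(NA_real_, n_node_total)
      ann[[k]][num] <<- annot[[k]]
    }
  }
  assign_num <- function(nd) {
    # numbers on entry: edges are appended in cladewise (preorder) order
    if (!length(nd$children)) {
      tip_i <<- tip_i + 1L
      num <- tip_i
    } else {
      int_i <<- int_i + 1L
      num <- n_tip + int_i
      node_label[int_i] <<- nd$label
    }
    set_ann(num, nd$annot)
    num
  }
  emit <- function(nd, num) {
    for (ch in nd$children) {
      ch_num <- assign_num(ch)
      edge_i <<- edge_i + 1L
      edge[edge_i, ] <<- c(num, ch_num)
      edge_len[edge_i] <<- ch$length
      if (length(ch$children)) emit(ch, ch_num)
    }
  }
  root_num <- assign_num(root)   # force before emit: lazy evaluation
  emit(root, root_num)
  tr <- structure(list(edge = edge, tip.label = tips, Nnode = n_int),
                  class = "phylo", order = "cladewise")
  if (!all(is.na(edge_len))) tr$edge.length <- ifelse(is.na(edge_len), 0, edge_len)
  if (any(nzchar(node_label))) tr$node.label <- node_label
  attr(tr, "node_annotations") <- ann
  tr
}

#' Posterior trace I/O
#'
#' A `posterior_trace` is a data.frame of retained MCMC iterations (rows) by
#' named parameters (columns), with attributes `thin` and `burnin_frac`.
#' On disk it is a plain TSV with a header row.
#'
#' @param trace A `posterior_trace` data.frame.
#' @param path File path.
#' @return `read_trace` returns a `posterior_trace`.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
#' @param thin,burnin_frac Chain thinning interval and burn-in fraction
#'   recorded alongside the samples.
posterior_trace <- function(trace, thin = 1L, burnin_frac = 0) {
  trace <- as.data.frame(trace)
  if (!all(vapply(trace, is.numeric, TRUE))) stop("trace must be numeric")
  if (nrow(trace) && any(!is.finite(as.matrix(trace))))
    stop("trace contains non-finite values")
  structure(trace, class = c("posterior_trace", "data.frame"),
            thin = as.integer(thin), burnin_frac = burnin_frac)
}

#' @rdname trace_io
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 1) {
    nfields <- lengths(strsplit(lines, "\t", fixed = TRUE))
    if (length(unique(nfields)) != 1)
      stop("ragged trace file: rows have differing field counts")
  }
  posterior_trace(utils::read.delim(path, check.names = FALSE))
}
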