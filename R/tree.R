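# Rooted traversal views ("tree_view") index tips 1..m and inner nodes
# m+1..2m-1; unrooted trees ("unrooted_tree") keep an undirected edge list
# with the same tip numbering and m-2 inner nodes.

.new_tree_view <- function(tip_labels, children, brlen, root) {
  m <- length(tip_labels)
  n_nodes <- nrow(children)
  parent <- rep.int(NA_integer_, n_nodes)
  for (u in seq_len(n_nodes)) {
    for (ch in children[u, ]) if (!is.na(ch)) parent[ch] <- u
  }
  # reverse preorder: every node appears after both of its children
  stack <- root; pre <- integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    pre <- c(pre, u)
    if (!is.na(children[u, 1L])) stack <- c(stack, children[u, 2L], children[u, 1L])
  }
  postorder <- rev(pre)
  postorder <- postorder[postorder > m]
  structure(list(tip_labels = tip_labels, m = m, n_nodes = n_nodes,
                 children = children, brlen = brlen, parent = parent,
                 postorder = postorder, root = root),
            class = "tree_view")
}

#' @export
print.tree_view <- function(x, ...) {
  cat("tree_view:", x$m, "tips,", x$n_nodes - x$m, "inner nodes, root =",
      x$root, "\n")
  invisible(x)
}

#' @export
print.unrooted_tree <- function(x, ...) {
  cat("unrooted_tree:", length(x$tip_labels), "tips,",
      x$n_nodes - length(x$tip_labels), "inner nodes\n")
  invisible(x)
}

.phylo_root <- function(phy) {
  setdiff(phy$edge[, 1], phy$edge[, 2])[1]
}

.view_from_phylo <- function(phy) {
  m <- length(phy$tip.label)
  n_nodes <- m + phy$Nnode
  children <- matrix(NA_integer_, n_nodes, 2L)
  brlen <- matrix(NA_real_, n_nodes, 2L)
  for (e in seq_len(nrow(phy$edge))) {
    u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
    slot <- if (is.na(children[u, 1L])) 1L else 2L
    children[u, slot] <- v
    brlen[u, slot] <- phy$edge.length[e]
  }
  .new_tree_view(phy$tip.label, children, brlen, .phylo_root(phy))
}

#' Parse a Newick tree
#'
#' Rooted binary input yields a `tree_view` ready for likelihood evaluation;
#' unrooted (basally trifurcating) input yields an `unrooted_tree` that must
#' be rooted with [root_at_terminal_edge()] first. Multifurcations are
#' resolved deterministically into binary nodes connected by zero-length
#' edges; missing branch lengths default to 0 with a warning.
#'
#' @param text Newick string.
#' @return A `tree_view` or `unrooted_tree`.
#' @export
parse_newick <- function(text) {
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("malformed Newick string")
  if (anyDuplicated(phy$tip.label)) stop("duplicate taxon labels in tree")
  if (!ape::is.binary(phy)) {
    phy <- ape::multi2di(phy, random = FALSE)
  }
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    phy$edge.length <- rep.int(0, nrow(phy$edge))
  } else if (anyNA(phy$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  if (any(phy$edge.length < 0) || any(!is.finite(phy$edge.length))) {
    stop("branch lengths must be finite and non-negative")
  }
  m <- length(phy$tip.label)
  root <- .phylo_root(phy)
  n_root_children <- sum(phy$edge[, 1] == root)
  if (n_root_children == 2L) {
    .view_from_phylo(phy)
  } else {
    edges <- phy$edge
    structure(list(tip_labels = phy$tip.label,
                   n_nodes = m + phy$Nnode,
                   edges = edges, lengths = phy$edge.length),
              class = "unrooted_tree")
  }
}

#' Collapse a rooted view into an unrooted edge list
#'
#' The root (degree-2) node is removed and its two incident edges merged,
#' summing their lengths. Inner nodes are renumbered m+1.. contiguously.
#'
#' @param x A `tree_view` or `unrooted_tree` (returned unchanged).
#' @return An `unrooted_tree`.
#' @export
as_unrooted <- function(x) {
  if (inherits(x, "unrooted_tree")) return(x)
  stopifnot(inherits(x, "tree_view"))
  m <- x$m
  edges <- NULL; lengths <- NULL
  for (u in seq_len(x$n_nodes)) {
    for (s in 1:2) {
      ch <- x$children[u, s]
      if (!is.na(ch)) {
        edges <- rbind(edges, c(u, ch)); lengths <- c(lengths, x$brlen[u, s])
      }
    }
  }
  r <- x$root
  ri <- which(edges[, 1] == r)
  a <- edges[ri[1], 2]; b <- edges[ri[2], 2]
  merged_len <- lengths[ri[1]] + lengths[ri[2]]
  keep <- setdiff(seq_len(nrow(edges)), ri)
  edges <- rbind(edges[keep, , drop = FALSE], c(a, b))
  lengths <- c(lengths[keep], merged_len)
  # renumber inner nodes (dropping the old root) to m+1..2m-2
  old_inner <- sort(setdiff(unique(as.vector(edges)), seq_len(m)))
  map <- integer(x$n_nodes); map[seq_len(m)] <- seq_len(m)
  map[old_inner] <- m + seq_along(old_inner)
  edges[] <- map[edges]
  structure(list(tip_labels = x$tip_labels, n_nodes = m + length(old_inner),
                 edges = edges, lengths = lengths),
            class = "unrooted_tree")
}

.adjacency <- function(ut) {
  adj <- vector("list", ut$n_nodes)
  for (e in seq_len(nrow(ut$edges))) {
    a <- ut$edges[e, 1]; b <- ut$edges[e, 2]; len <- ut$lengths[e]
    adj[[a]] <- rbind(adj[[a]], c(b, len))
    adj[[b]] <- rbind(adj[[b]], c(a, len))
  }
  adj
}

#' Root a tree on the pendant edge of a taxon
#'
#' Places a virtual root at the tip-side end of the taxon's pendant edge: the
#' root's two children are the tip itself (zero-length edge) and the tip's
#' former neighbour, which keeps the full pendant edge length. Under a
#' reversible model the likelihood is identical for every such rooting.
#'
#' @param tree An `unrooted_tree` or `tree_view`.
#' @param taxon Taxon label at whose pendant edge the virtual root is placed.
#' @return A strictly binary `tree_view` with `2m - 1` nodes.
#' @export
root_at_terminal_edge <- function(tree, taxon) {
  ut <- as_unrooted(tree)
  m <- length(ut$tip_labels)
  t_id <- match(taxon, ut$tip_labels)
  if (is.na(t_id)) stop("unknown taxon '", taxon, "'")
  adj <- .adjacency(ut)
  n_nodes <- m + (ut$n_nodes - m) + 1L  # + virtual root
  children <- matrix(NA_integer_, n_nodes, 2L)
  brlen <- matrix(NA_real_, n_nodes, 2L)
  root <- n_nodes
  p_old <- adj[[t_id]][1, 1]; pend_len <- adj[[t_id]][1, 2]
  # DFS away from the tip, relabelling old inner nodes in discovery order
  map <- integer(ut$n_nodes); map[seq_len(m)] <- seq_len(m)
  next_id <- m
  new_id <- function(old) {
    if (old <= m) return(map[old])
    if (map[old] == 0L) {
      next_id <<- next_id + 1L
      map[old] <<- next_id
    }
    map[old]
  }
  children[root, ] <- c(t_id, NA_integer_)
  brlen[root, 1L] <- 0
  stack <- list(c(p_old, t_id, root, 2L))  # node, came-from, parent-new, slot
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- fr[1]; from <- fr[2]; par_new <- fr[3]; slot <- fr[4]
    id <- new_id(node)
    children[par_new, slot] <- id
    brlen[par_new, slot] <- if (par_new == root) pend_len else
      adj[[node]][adj[[node]][, 1] == from, 2][1]
    if (node > m) {
      nb <- adj[[node]]
      nb <- nb[nb[, 1] != from, , drop = FALSE]
      if (nrow(nb) != 2L) stop("tree is not binary at node ", node)
      stack[[length(stack) + 1L]] <- c(nb[1, 1], node, id, 1L)
      stack[[length(stack) + 1L]] <- c(nb[2, 1], node, id, 2L)
    }
  }
  # brlen for stacked children references parent's adjacency; fix: length of
  # edge (par, node) was taken from adj[[node]] looking back at `from`, which
  # is the same undirected edge. (handled above)
  .new_tree_view(ut$tip_labels, children, brlen, root)
}

.view_to_phylo <- function(view) {
  is_inner <- !is.na(view$children[, 1L])
  edges <- NULL; lens <- NULL
  for (u in which(is_inner)) {
    for (s in 1:2) {
      edges <- rbind(edges, c(u, view$children[u, s]))
      lens <- c(lens, view$brlen[u, s])
    }
  }
  phy <- list(edge = edges, edge.length = lens, tip.label = view$tip_labels,
              Nnode = sum(is_inner))
  class(phy) <- "phylo"
  phy
}

#' Serialise a tree to Newick
#'
#' @param tree A `tree_view` or `unrooted_tree`.
#' @return Newick string with branch lengths.
#' @export
write_newick <- function(tree) {
  if (inherits(tree, "tree_view")) {
    return(ape::write.tree(.view_to_phylo(tree)))
  }
  stopifnot(inherits(tree, "unrooted_tree"))
  m <- length(tree$tip_labels)
  adj <- .adjacency(tree)
  start <- m + 1L  # an inner node as the display root
  sub <- function(node, from) {
    nb <- adj[[node]]
    nb <- nb[nb[, 1] != from, , drop = FALSE]
    if (node <= m) return(tree$tip_labels[node])
    parts <- vapply(seq_len(nrow(nb)), function(i) {
      paste0(sub(nb[i, 1], node), ":", format(nb[i, 2], digits = 15))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(sub(start, 0L), ";")
}

#' Mark inner nodes (and all their ancestors) for recomputation
#'
#' Returns the upward closure of `nodes`: every ancestor up to the root is
#' included, so a partial traversal over the set leaves no stale conditional
#' likelihoods above a recomputed node.
#'
#' @param tree A `tree_view`.
#' @param nodes Inner node ids to invalidate.
#' @return A `dirty_set` with fields `nodes` (ids) and `postorder`
#'   (traversal order restricted to the set).
#' @export
mark_dirty <- function(tree, nodes) {
  stopifnot(inherits(tree, "tree_view"))
  nodes <- unique(as.integer(nodes))
  if (any(nodes <= tree$m | nodes > tree$n_nodes)) {
    stop("dirty nodes must be inner nodes of the tree")
  }
  closed <- integer(0)
  for (u in nodes) {
    while (!is.na(u) && !(u %in% closed)) {
      closed <- c(closed, u)
      u <- tree$parent[u]
    }
  }
  structure(list(nodes = sort(closed),
                 postorder = tree$postorder[tree$postorder %in% closed]),
            class = "dirty_set")
}

#' Sample a dirty set by a random walk over adjacent inner nodes
#'
#' Emulates the conditional-likelihood invalidation pattern of local tree
#' rearrangements: start from a random pair of adjacent inner nodes and, with
#' continuation probability `p` per step, extend the path by one unvisited
#' inner neighbour at each end until the walk stops or no inner node remains.
#'
#' @param tree A `tree_view`.
#' @param p Continuation probability (default 0.95).
#' @return A `dirty_set` (upward-closed, via [mark_dirty()]).
#' @export
sample_dirty_walk <- function(tree, p = 0.95) {
  m <- tree$m
  inner <- (m + 1L):tree$n_nodes
  neigh <- function(u) {
    nb <- c(tree$parent[u], tree$children[u, ])
    nb[!is.na(nb) & nb > m]
  }
  u <- sample(inner, 1L)
  nb <- neigh(u)
  if (!length(nb)) return(mark_dirty(tree, u))
  v <- if (length(nb) == 1L) nb else sample(nb, 1L)
  visited <- c(u, v); ends <- c(u, v)
  repeat {
    if (stats::runif(1) > p) break
    new_ends <- integer(0); grown <- FALSE
    for (e in ends) {
      cand <- setdiff(neigh(e), visited)
      if (length(cand)) {
        nxt <- if (length(cand) == 1L) cand else sample(cand, 1L)
        visited <- c(visited, nxt); new_ends <- c(new_ends, nxt); grown <- TRUE
      }
    }
    if (!grown) break
    ends <- new_ends
  }
  mark_dirty(tree, visited)
}
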