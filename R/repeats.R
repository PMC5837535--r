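# Site-repeat detection and repeat-aware likelihood computation.
#
# Per node u with children v, w, two sites are repeats iff their (phi_v,
# phi_w) child-identifier pairs coincide. Identifiers are dense integers
# (1..maxid, first-occurrence order) minted through a bounded flat lookup
# buffer M with clean-list validation, so the buffer is allocated once and
# reused for every node without clearing. One conditional likelihood is then
# computed per identifier class and stored in the compressed LH array.

#' Bijective pairing of two identifiers
#'
#' @param a First identifier (>= 1).
#' @param b Second identifier, in `[1, base]`.
#' @param base Range of `b`.
#' @return `(a - 1) * base + b`; distinct pairs map to distinct values.
#' @export
tau <- function(a, b, base) {
  (a - 1L) * as.integer(base) + b
}

#' Assign repeat-class identifiers at a cherry
#'
#' Each site gets the paired identifier `tau` of its two encoded tip states,
#' renumbered densely by first occurrence: sites with equal tip pairs share
#' an identifier and `maxid` is the number of distinct pairs.
#'
#' @param xv,xw Encoded tip rows (masks in `[1, 15]`) of equal length.
#' @return List with `phi` (identifiers) and `maxid`.
#' @export
assign_identifiers_cherry <- function(xv, xw) {
  stopifnot(length(xv) == length(xw))
  pair <- tau(as.integer(xv), as.integer(xw), 16L)
  phi <- match(pair, unique(pair))
  list(phi = phi, maxid = max(phi), fallback = FALSE)
}

#' Create a bounded repeat lookup table
#'
#' The flat integer buffer `M` (at most `tsize` entries, grown lazily and
#' reused across nodes) is paired with a clean list holding, per identifier,
#' the buffer position and assignment epoch that minted it; an `M` entry is
#' valid only if its clean record matches, so stale entries from earlier
#' nodes or traversals are treated as empty without ever clearing `M`.
#'
#' @param tsize Maximum number of table entries (default 5e7, i.e. 200 MB at
#'   4 bytes per entry; `Inf` for unbounded).
#' @return An environment of class `repeat_table`.
#' @export
new_repeat_table <- function(tsize = 5e7) {
  tab <- new.env(parent = emptyenv())
  tab$tsize <- tsize
  tab$M <- integer(0)
  tab$clean_pos <- numeric(0)
  tab$clean_epoch <- numeric(0)
  tab$epoch <- 0
  class(tab) <- "repeat_table"
  tab
}

#' Assign identifiers at a tip-inner or inner-inner node via the lookup table
#'
#' Queries `M` at position `(phi_v(i) - 1) * maxid_w + phi_w(i)` per site.
#' First occurrences mint a fresh identifier (a counter starting at 1) and
#' record it in the clean list; repeats inherit the stored identifier. If
#' `maxid_v * maxid_w` exceeds the table bound, repeat detection is skipped
#' for this node (FALLBACK): every site becomes its own class
#' (`phi = 1..n`, `maxid = n`), which in turn forces FALLBACK at ancestors.
#'
#' @param phi_v,phi_w Child identifier vectors (for a tip child, the encoded
#'   states).
#' @param maxid_v,maxid_w Maximum identifier values of the children.
#' @param table A [new_repeat_table()].
#' @param tsize Table bound; defaults to the table's own.
#' @return List with `phi`, `maxid`, `fallback`.
#' @export
assign_identifiers_inner <- function(phi_v, maxid_v, phi_w, maxid_w,
                                     table, tsize = table$tsize) {
  n <- length(phi_v)
  stopifnot(length(phi_w) == n)
  need <- as.numeric(maxid_v) * as.numeric(maxid_w)
  if (need > tsize) {
    return(list(phi = seq_len(n), maxid = n, fallback = TRUE))
  }
  if (need > .Machine$integer.max) {
    stop("lookup table of ", need, " entries exceeds addressable size")
  }
  need <- as.integer(need)
  M <- table$M
  if (length(M) < need) M <- c(M, integer(need - length(M)))
  clean_pos <- table$clean_pos
  clean_epoch <- table$clean_epoch
  if (length(clean_pos) < n) {
    clean_pos <- c(clean_pos, numeric(n - length(clean_pos)))
    clean_epoch <- c(clean_epoch, numeric(n - length(clean_epoch)))
  }
  epoch <- table$epoch + 1
  d_all <- (as.integer(phi_v) - 1L) * as.integer(maxid_w) + as.integer(phi_w)
  phi <- integer(n)
  ident <- 0L
  for (i in seq_len(n)) {
    d <- d_all[i]
    val <- M[d]
    if (val > 0L && clean_pos[val] == d && clean_epoch[val] == epoch) {
      phi[i] <- val
    } else {
      ident <- ident + 1L
      M[d] <- ident
      clean_pos[ident] <- d
      clean_epoch[ident] <- epoch
      phi[i] <- ident
    }
  }
  table$M <- M
  table$clean_pos <- clean_pos
  table$clean_epoch <- clean_epoch
  table$epoch <- epoch
  list(phi = phi, maxid = ident, fallback = FALSE)
}

# one shared 4 x k x 15 tip "LH" array: entry [, c, mask] is the tip CLV of
# that encoded mask, identical across categories
.tip_lh <- function(k) {
  tipmat <- vapply(1:15, tip_clv, numeric(4))
  aperm(array(tipmat, dim = c(4, 15, k)), c(1, 3, 2))
}

#' Create a repeat-aware likelihood engine
#'
#' The engine owns the rooted traversal view, the encoded alignment, the
#' bounded lookup table and the per-node identifier and compressed-CLV state
#' reused across calls.
#'
#' @param tree A `tree_view` (see [parse_newick()], [root_at_terminal_edge()]).
#' @param alignment A [plf_alignment()] whose taxa match the tree tips.
#' @param tsize Lookup-table bound in entries (default 5e7 = 200 MB at
#'   4 bytes/entry).
#' @param mode `"SRDT"` (identifiers recomputed every call; dynamic
#'   topologies) or `"SRCT"` (identifiers computed once and cached; fixed
#'   topology, e.g. model-parameter optimisation).
#' @return An environment of class `repeat_engine`.
#' @export
new_repeat_engine <- function(tree, alignment, tsize = 5e7,
                              mode = c("SRDT", "SRCT")) {
  stopifnot(inherits(tree, "tree_view"), inherits(alignment, "plf_alignment"))
  mode <- match.arg(mode)
  ord <- match(tree$tip_labels, alignment$taxa)
  if (anyNA(ord)) stop("alignment taxa do not match tree tips")
  eng <- new.env(parent = emptyenv())
  eng$tree <- tree
  eng$aln <- alignment
  eng$ord <- ord
  eng$tsize <- tsize
  eng$mode <- mode
  eng$table <- new_repeat_table(tsize)
  eng$ids <- vector("list", tree$n_nodes)
  eng$maxid <- rep.int(NA_integer_, tree$n_nodes)
  eng$fallback <- rep.int(FALSE, tree$n_nodes)
  for (tip in seq_len(tree$m)) {
    eng$ids[[tip]] <- as.integer(alignment$data[ord[tip], ])
    eng$maxid[tip] <- max(eng$ids[[tip]])
  }
  eng$lh <- vector("list", tree$n_nodes)
  eng$scale <- vector("list", tree$n_nodes)
  eng$counts <- rep.int(0L, tree$n_nodes)
  eng$has_ids <- FALSE
  eng$last_result <- NULL
  class(eng) <- "repeat_engine"
  eng
}

#' @export
print.repeat_engine <- function(x, ...) {
  cat("repeat_engine (", x$mode, "): ", x$tree$m, " tips, ",
      ncol(x$aln$data), " site patterns, tsize = ", format(x$tsize),
      "\n", sep = "")
  invisible(x)
}

.engine_assign_node <- function(eng, u) {
  v <- eng$tree$children[u, 1]; w <- eng$tree$children[u, 2]
  res <- assign_identifiers_inner(eng$ids[[v]], eng$maxid[v],
                                  eng$ids[[w]], eng$maxid[w], eng$table)
  eng$ids[[u]] <- res$phi
  eng$maxid[u] <- res$maxid
  eng$fallback[u] <- res$fallback
  invisible(res)
}

.engine_compute_node <- function(eng, u, model, tip_lh, scaling = TRUE) {
  tree <- eng$tree
  v <- tree$children[u, 1]; w <- tree$children[u, 2]
  phi_u <- eng$ids[[u]]; maxid_u <- eng$maxid[u]
  reps <- match(seq_len(maxid_u), phi_u)  # first site of each class
  fetch <- function(x, sel) {
    if (x <= tree$m) {
      list(lh = tip_lh[, , eng$ids[[x]][sel], drop = FALSE],
           scale = rep.int(0L, length(sel)))
    } else {
      list(lh = eng$lh[[x]][, , eng$ids[[x]][sel], drop = FALSE],
           scale = eng$scale[[x]][eng$ids[[x]][sel]])
    }
  }
  cv <- fetch(v, reps); cw <- fetch(w, reps)
  arr <- inner_clv(cv$lh, cw$lh, .edge_P(model, tree$brlen[u, 1]),
                   .edge_P(model, tree$brlen[u, 2]))
  sc <- cv$scale + cw$scale
  if (scaling) {
    cls_max <- apply(arr, 3, max)
    low <- which(cls_max < .scale_threshold & cls_max > 0)
    if (length(low)) {
      arr[, , low] <- arr[, , low, drop = FALSE] * .scale_factor
      sc[low] <- sc[low] + 1L
    }
  }
  eng$lh[[u]] <- arr
  eng$scale[[u]] <- sc
  eng$counts[u] <- maxid_u
  invisible(NULL)
}

.engine_root_likelihood <- function(eng, model) {
  tree <- eng$tree
  arr <- eng$lh[[tree$root]]
  class_vals <- apply(arr, 3, function(s) {
    mean(colSums(model$frequencies * matrix(s, nrow = 4)))
  })
  phi_r <- eng$ids[[tree$root]]
  .root_loglik(class_vals[phi_r], eng$scale[[tree$root]][phi_r],
               eng$aln$weights)
}

.engine_run <- function(eng, model, nodes, reuse_ids, scaling = TRUE) {
  tip_lh <- .tip_lh(model$n_categories)
  for (u in nodes) {
    if (!reuse_ids) .engine_assign_node(eng, u)
    .engine_compute_node(eng, u, model, tip_lh, scaling)
  }
  eng$has_ids <- TRUE
  eng$last_ops <- sum(eng$counts[nodes])
  eng$last_result <- .engine_root_likelihood(eng, model)
  eng$last_result
}

#' Repeat-aware full traversal (REPEATS-FULL)
#'
#' Post-order over all inner nodes: per node, repeat-class identifiers are
#' assigned through the bounded lookup table, then exactly one conditional
#' likelihood is computed per class and stored in the compressed LH array
#' (duplicates are never stored). The log-likelihood is read off the root's
#' LH entries, honouring site weights. Identical to the reference
#' [likelihood_rooted()] up to floating-point ordering.
#'
#' @inheritParams new_repeat_engine
#' @param model A [subst_model()].
#' @param engine Optional engine from a previous call. In `"SRCT"` mode its
#'   cached identifier map is reused (only branch lengths / model parameters
#'   may change); in `"SRDT"` mode identifiers are recomputed.
#' @param scaling Apply per-class underflow rescaling (default TRUE).
#' @return A `repeats_result`: list with `result` (a `likelihood_result`),
#'   `ids`, `maxid`, `fallback`, `counts` (per-node CLV computations),
#'   `clv_computations` (their sum), `table_entries` (buffer entries
#'   allocated) and the `engine` for reuse.
#' @export
repeats_full_traversal <- function(tree, alignment, model, tsize = 5e7,
                                   mode = c("SRDT", "SRCT"), engine = NULL,
                                   scaling = TRUE) {
  mode <- match.arg(mode)
  if (is.null(engine)) {
    engine <- new_repeat_engine(tree, alignment, tsize, mode)
  } else {
    stopifnot(inherits(engine, "repeat_engine"))
    if (!is.null(tree)) {
      if (!identical(engine$tree$children, tree$children) ||
          engine$tree$root != tree$root) {
        if (engine$mode == "SRCT" && engine$has_ids) {
          stop("SRCT engine cannot change topology; rebuild the engine")
        }
      }
      engine$tree <- tree
      engine$ord <- match(tree$tip_labels, engine$aln$taxa)
      for (tip in seq_len(tree$m)) {
        engine$ids[[tip]] <- as.integer(engine$aln$data[engine$ord[tip], ])
        engine$maxid[tip] <- max(engine$ids[[tip]])
      }
    }
  }
  reuse <- engine$mode == "SRCT" && engine$has_ids
  res <- .engine_run(engine, model, engine$tree$postorder, reuse, scaling)
  structure(list(result = res,
                 ids = engine$ids, maxid = engine$maxid,
                 fallback = engine$fallback, counts = engine$counts,
                 clv_computations = sum(engine$counts),
                 table_entries = length(engine$table$M),
                 root = engine$tree$root, m = engine$tree$m,
                 engine = engine),
            class = "repeats_result")
}

#' @export
print.repeats_result <- function(x, ...) {
  cat("repeats_result: logL =", format(x$result$loglik, digits = 12),
      "| CLV computations =", x$clv_computations,
      "| fallback nodes =", sum(x$fallback), "\n")
  invisible(x)
}

#' Partial update after a local tree change
#'
#' Recomputes identifiers (SRDT only; SRCT identifiers are cached) and
#' compressed CLVs for the dirty nodes alone, in post-order. The clean-list
#' epochs guarantee that stale lookup-table entries from earlier traversals
#' are never read. The result equals a fresh full traversal of the modified
#' tree.
#'
#' @param engine A `repeat_engine` after at least one full traversal.
#' @param dirty A [mark_dirty()] set (upward-closed).
#' @param model A [subst_model()].
#' @param tree Optional `tree_view` with identical topology but changed
#'   branch lengths; changed edges must lie under dirty nodes.
#' @inheritParams repeats_full_traversal
#' @return The `likelihood_result`; engine counters are updated in place.
#' @export
partial_update <- function(engine, dirty, model, tree = NULL, scaling = TRUE) {
  stopifnot(inherits(engine, "repeat_engine"), inherits(dirty, "dirty_set"))
  if (!engine$has_ids) stop("run repeats_full_traversal() before partial_update()")
  for (u in dirty$nodes) {
    p <- engine$tree$parent[u]
    if (!is.na(p) && !(p %in% dirty$nodes)) {
      stop("dirty set is not upward-closed at node ", u)
    }
  }
  if (!is.null(tree)) {
    if (!identical(engine$tree$children, tree$children)) {
      stop("partial_update requires an identical topology")
    }
    engine$tree <- tree
  }
  if (!length(dirty$nodes)) {
    engine$last_ops <- 0L
    return(engine$last_result)
  }
  tip_lh <- .tip_lh(model$n_categories)
  reuse <- engine$mode == "SRCT"
  for (u in dirty$postorder) {
    if (!reuse) .engine_assign_node(engine, u)
    .engine_compute_node(engine, u, model, tip_lh, scaling)
  }
  engine$last_ops <- sum(engine$counts[dirty$postorder])
  engine$last_result <- .engine_root_likelihood(engine, model)
  engine$last_result
}

#' Fraction of sites that are repeats, pooled over all inner nodes
#'
#' With an unbounded lookup table (so every repeat is found), computes
#' `100 * sum_u (n - maxid[u]) / (n * #inner nodes)` where `n` is the
#' uncompressed site count. This is the per-tree "repeats %" statistic.
#'
#' @param tree A `tree_view` or `unrooted_tree`.
#' @param alignment A [plf_alignment()].
#' @param rooting Taxon label for virtual rooting (required for an
#'   `unrooted_tree`).
#' @return Percentage in `[0, 100]`.
#' @export
repeat_fraction <- function(tree, alignment, rooting = NULL) {
  if (inherits(tree, "unrooted_tree")) {
    if (is.null(rooting)) rooting <- tree$tip_labels[1]
    tree <- root_at_terminal_edge(tree, rooting)
  }
  n_total <- sum(alignment$weights)
  comp <- compress_patterns(alignment)
  eng <- new_repeat_engine(tree, comp, tsize = Inf)
  for (u in tree$postorder) .engine_assign_node(eng, u)
  inner <- tree$postorder
  100 * sum(n_total - eng$maxid[inner]) / (n_total * length(inner))
}

#' Memory footprint report for repeat-aware CLV storage
#'
#' @param m Number of taxa.
#' @param n Number of alignment sites.
#' @param maxid Per-node unique-class counts for the `m - 2` non-root inner
#'   nodes (a virtual root's CLV is not stored when the likelihood is
#'   evaluated at an edge); `NULL` to omit the compressed figure.
#' @param k Number of rate categories (default 4).
#' @param table_entries Lookup-table entries in use.
#' @return List with `uncompressed_bytes` (the standard
#'   `8 * 4 * k * (m - 2) * n` CLV footprint), `compressed_bytes`
#'   (`sum(maxid) * 8 * 4 * k`), `identifier_bytes` (4 bytes per site per
#'   inner node), `lookup_table_bytes`, and
#'   `clv_to_identifier_value_ratio` (`4 * k` stored values per site versus
#'   one identifier).
#' @export
memory_estimate <- function(m, n, maxid = NULL, k = 4, table_entries = 0) {
  out <- list(
    uncompressed_bytes = 8 * 4 * k * (m - 2) * n,
    compressed_bytes = if (is.null(maxid)) NA_real_ else
      sum(maxid) * 8 * 4 * k,
    identifier_bytes = 4 * n * (m - 1),
    lookup_table_bytes = 4 * table_entries,
    clv_to_identifier_value_ratio = 4 * k
  )
  class(out) <- "memory_report"
  out
}

#' @export
print.memory_report <- function(x, ...) {
  cat("uncompressed CLVs:", x$uncompressed_bytes, "bytes\n")
  if (!is.na(x$compressed_bytes)) {
    cat("compressed CLVs:  ", x$compressed_bytes, "bytes\n")
  }
  cat("identifier lists: ", x$identifier_bytes, "bytes\n")
  cat("lookup table:     ", x$lookup_table_bytes, "bytes\n")
  invisible(x)
}
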