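# Reference (uncompressed) Felsenstein pruning. One conditional likelihood
# vector per node, site and rate category; per-site power-of-two rescaling
# guards against underflow on deep trees.

.scale_threshold <- 2^-256
.scale_factor <- 2^256
.log_scale_factor <- 256 * log(2)

#' Tip conditional likelihood vector for an encoded state
#'
#' @param x Encoded state mask in `[1, 15]`.
#' @return 0/1 vector of length 4: entry `s` is 1 iff bit `s` is set in `x`.
#' @export
tip_clv <- function(x) {
  as.numeric(bitwAnd(x, c(1L, 2L, 4L, 8L)) > 0L)
}

.tip_clv_matrix <- function(row) {
  # 4 x n 0/1 matrix for a whole encoded sequence
  vapply(row, tip_clv, numeric(4))
}

#' Combine two child conditional likelihoods into the parent's (one node step)
#'
#' For each state `s` and rate category: the product of the two child sums
#' `sum_sv P_v[s, sv] L_v(sv)` and `sum_sw P_w[s, sw] L_w(sw)`.
#'
#' @param clv_v,clv_w Child CLV arrays, `4 x k x n`.
#' @param P_v,P_w Lists of `k` transition matrices (one per rate category)
#'   for the two child edges.
#' @return A `4 x k x n` array.
#' @export
inner_clv <- function(clv_v, clv_w, P_v, P_w) {
  k <- dim(clv_v)[2]; n <- dim(clv_v)[3]
  out <- array(0, dim = c(4, k, n))
  for (c in seq_len(k)) {
    out[, c, ] <- (P_v[[c]] %*% clv_v[, c, , drop = TRUE]) *
      (P_w[[c]] %*% clv_w[, c, , drop = TRUE])
  }
  out
}

.edge_P <- function(model, t) {
  lapply(model$category_rates, function(r) transition_matrix(model, t, r))
}

#' Compute all conditional likelihood vectors of a rooted view
#'
#' @param tree A `tree_view`.
#' @param alignment A [plf_alignment()] whose taxa match the tree tips.
#' @param model A [subst_model()].
#' @param scaling Apply per-site underflow rescaling (default TRUE).
#' @return A `clv_store`: list with `clv` (per-node `4 x k x n` arrays) and
#'   `scale_exp` (per-node integer rescale counts per site).
#' @export
compute_clvs <- function(tree, alignment, model, scaling = TRUE) {
  stopifnot(inherits(tree, "tree_view"), inherits(alignment, "plf_alignment"))
  ord <- match(tree$tip_labels, alignment$taxa)
  if (anyNA(ord)) stop("alignment taxa do not match tree tips")
  n <- ncol(alignment$data); k <- model$n_categories
  clv <- vector("list", tree$n_nodes)
  scale_exp <- matrix(0L, tree$n_nodes, n)
  for (tip in seq_len(tree$m)) {
    tipmat <- .tip_clv_matrix(alignment$data[ord[tip], ])
    # replicate each site's 0/1 vector across the k rate categories
    clv[[tip]] <- aperm(array(tipmat, dim = c(4, n, k)), c(1, 3, 2))
  }
  for (u in tree$postorder) {
    v <- tree$children[u, 1]; w <- tree$children[u, 2]
    P_v <- .edge_P(model, tree$brlen[u, 1])
    P_w <- .edge_P(model, tree$brlen[u, 2])
    arr <- inner_clv(clv[[v]], clv[[w]], P_v, P_w)
    scale_exp[u, ] <- scale_exp[v, ] + scale_exp[w, ]
    if (scaling) {
      site_max <- apply(arr, 3, max)
      low <- which(site_max < .scale_threshold & site_max > 0)
      if (length(low)) {
        arr[, , low] <- arr[, , low, drop = FALSE] * .scale_factor
        scale_exp[u, low] <- scale_exp[u, low] + 1L
      }
    }
    clv[[u]] <- arr
  }
  structure(list(clv = clv, scale_exp = scale_exp), class = "clv_store")
}

.root_loglik <- function(root_vals, root_exp, weights) {
  # root_vals: per-site likelihood already averaged over categories
  bad <- which(root_vals <= 0)
  if (length(bad)) {
    stop("numerical-underflow error: non-positive likelihood at site ",
         bad[1])
  }
  per_site <- log(root_vals) + root_exp * .log_scale_factor
  structure(list(loglik = sum(weights * per_site), per_site = per_site),
            class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat("log-likelihood:", format(x$loglik, digits = 12), "\n")
  invisible(x)
}

#' Rooted-tree log-likelihood (reference path)
#'
#' Per site: the conditional likelihoods at the root are averaged over rate
#' categories (equal category weights) and summed against the stationary
#' frequencies; site weights and rescaling exponents are honoured in log
#' space.
#'
#' @inheritParams compute_clvs
#' @param clvs Optional precomputed [compute_clvs()] store.
#' @return A `likelihood_result` with `loglik` (natural log) and `per_site`.
#' @export
likelihood_rooted <- function(tree, alignment, model, clvs = NULL,
                              scaling = TRUE) {
  if (is.null(clvs)) clvs <- compute_clvs(tree, alignment, model, scaling)
  arr <- clvs$clv[[tree$root]]
  k <- dim(arr)[2]
  vals <- apply(arr, 3, function(slice) {
    mean(colSums(model$frequencies * matrix(slice, nrow = 4)))
  })
  .root_loglik(vals, clvs$scale_exp[tree$root, ], alignment$weights)
}

#' Unrooted-tree log-likelihood evaluated at an edge
#'
#' Per site: `sum_su L_u(su) pi_su sum_sv P(su -> sv; theta_uv) L_v(sv)`,
#' where each endpoint's conditional likelihoods are taken over its side of
#' the edge. For a reversible model the result is identical for every edge.
#'
#' @param tree An `unrooted_tree`.
#' @param u,v Node ids of an edge of `tree`.
#' @inheritParams compute_clvs
#' @return A `likelihood_result`.
#' @export
likelihood_edge <- function(tree, u, v, alignment, model, scaling = TRUE) {
  stopifnot(inherits(tree, "unrooted_tree"))
  ord <- match(tree$tip_labels, alignment$taxa)
  if (anyNA(ord)) stop("alignment taxa do not match tree tips")
  m <- length(tree$tip_labels)
  n <- ncol(alignment$data); k <- model$n_categories
  adj <- .adjacency(tree)
  edge_row <- adj[[u]][adj[[u]][, 1] == v, , drop = FALSE]
  if (nrow(edge_row) == 0L) stop("(u, v) is not an edge of the tree")
  t_uv <- edge_row[1, 2]
  cache <- new.env(parent = emptyenv())
  dir_clv <- function(node, from) {
    key <- paste0(node, "<", from)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- if (node <= m) {
      tipmat <- .tip_clv_matrix(alignment$data[ord[node], ])
      list(arr = aperm(array(tipmat, dim = c(4, n, k)), c(1, 3, 2)),
           exp = rep.int(0L, n))
    } else {
      nb <- adj[[node]]
      nb <- nb[nb[, 1] != from, , drop = FALSE]
      a <- dir_clv(nb[1, 1], node); b <- dir_clv(nb[2, 1], node)
      arr <- inner_clv(a$arr, b$arr, .edge_P(model, nb[1, 2]),
                       .edge_P(model, nb[2, 2]))
      ex <- a$exp + b$exp
      if (scaling) {
        site_max <- apply(arr, 3, max)
        low <- which(site_max < .scale_threshold & site_max > 0)
        if (length(low)) {
          arr[, , low] <- arr[, , low, drop = FALSE] * .scale_factor
          ex[low] <- ex[low] + 1L
        }
      }
      list(arr = arr, exp = ex)
    }
    cache[[key]] <- res
    res
  }
  side_u <- dir_clv(u, v)
  side_v <- dir_clv(v, u)
  P_uv <- .edge_P(model, t_uv)
  vals <- numeric(n)
  for (c in seq_len(k)) {
    Lu <- matrix(side_u$arr[, c, ], nrow = 4)
    Lv <- matrix(side_v$arr[, c, ], nrow = 4)
    vals <- vals + colSums((model$frequencies * Lu) * (P_uv[[c]] %*% Lv))
  }
  vals <- vals / k
  .root_loglik(vals, side_u$exp + side_v$exp, alignment$weights)
}
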