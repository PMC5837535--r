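# Brute-force oracles and a sequence simulator. These deliberately share no
# computational code with the engine: the scalar likelihood oracle builds its
# own transition matrices (plain eigen of the unsymmetrised generator) and
# evaluates the pruning recursions with nested loops, and the repeat oracle
# compares raw column strings.

#' Tip ids below a node of a rooted view
#'
#' @param tree A `tree_view`.
#' @param node Node id.
#' @return Integer vector of tip ids in the subtree rooted at `node`.
#' @export
subtree_tips <- function(tree, node) {
  if (node <= tree$m) return(node)
  stack <- node; tips <- integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (u <= tree$m) tips <- c(tips, u) else stack <- c(stack, tree$children[u, ])
  }
  sort(tips)
}

#' Brute-force repeat classes at a node (oracle)
#'
#' Groups sites by exact equality of their alignment columns restricted to
#' the tips of the node's subtree, by string comparison. Two sites are
#' repeats at the node iff they land in the same class.
#'
#' @param tree A `tree_view`.
#' @param alignment A [plf_alignment()].
#' @param node Node id.
#' @return List of integer vectors (site indices), ordered by first
#'   occurrence.
#' @export
brute_force_repeats <- function(tree, alignment, node) {
  ord <- match(tree$tip_labels, alignment$taxa)
  tips <- subtree_tips(tree, node)
  sub <- alignment$data[ord[tips], , drop = FALSE]
  key <- apply(sub, 2, paste, collapse = "|")
  unname(split(seq_along(key), factor(key, levels = unique(key))))
}

#' Discrete-Gamma category rates by numerical quadrature (oracle)
#'
#' Integrates `x * dgamma(x; alpha, alpha)` over each equal-probability
#' quantile bin, independent of the closed form in [discretize_gamma()].
#'
#' @inheritParams discretize_gamma
#' @return `k` rate multipliers.
#' @export
gamma_rates_quadrature <- function(alpha, k) {
  qb <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha,
                      rate = alpha)
  qb[k + 1L] <- Inf
  vapply(seq_len(k), function(i) {
    stats::integrate(function(x) x * stats::dgamma(x, shape = alpha,
                                                   rate = alpha),
                     qb[i], qb[i + 1L], rel.tol = 1e-12)$value * k
  }, 0)
}

# transition matrices by plain (unsymmetrised) eigendecomposition
.oracle_P <- function(model, t, r) {
  rates <- model$rates; freq <- model$frequencies
  Q <- matrix(0, 4, 4)
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (e in 1:6) {
    i <- idx[e, 1]; j <- idx[e, 2]
    Q[i, j] <- rates[e] * freq[j]
    Q[j, i] <- rates[e] * freq[i]
  }
  for (i in 1:4) Q[i, i] <- -sum(Q[i, -i])
  Q <- Q / -sum(freq * diag(Q))
  es <- eigen(Q)
  P <- Re(es$vectors %*% diag(exp(es$values * t * r)) %*% solve(es$vectors))
  P
}

#' Scalar-loop phylogenetic likelihood oracle
#'
#' Plain nested-loop evaluation of the pruning recursions with no
#' vectorisation, compression or rescaling; intended for small instances
#' (roughly m <= 12, n <= 100) where no underflow occurs.
#'
#' @param tree A `tree_view`.
#' @param alignment A [plf_alignment()].
#' @param model A [subst_model()].
#' @return A `likelihood_result`.
#' @export
scalar_plf_oracle <- function(tree, alignment, model) {
  ord <- match(tree$tip_labels, alignment$taxa)
  if (anyNA(ord)) stop("alignment taxa do not match tree tips")
  n <- ncol(alignment$data)
  k <- model$n_categories
  L <- vector("list", tree$n_nodes)
  for (tip in seq_len(tree$m)) {
    arr <- array(0, dim = c(n, k, 4))
    row <- alignment$data[ord[tip], ]
    for (i in seq_len(n)) {
      for (c in seq_len(k)) {
        for (s in 1:4) {
          arr[i, c, s] <- if (bitwAnd(row[i], c(1L, 2L, 4L, 8L)[s]) > 0L) 1 else 0
        }
      }
    }
    L[[tip]] <- arr
  }
  for (u in tree$postorder) {
    v <- tree$children[u, 1]; w <- tree$children[u, 2]
    Pv <- lapply(model$category_rates, function(r)
      .oracle_P(model, tree$brlen[u, 1], r))
    Pw <- lapply(model$category_rates, function(r)
      .oracle_P(model, tree$brlen[u, 2], r))
    arr <- array(0, dim = c(n, k, 4))
    for (i in seq_len(n)) {
      for (c in seq_len(k)) {
        for (s in 1:4) {
          sv_sum <- 0
          for (sv in 1:4) sv_sum <- sv_sum + Pv[[c]][s, sv] * L[[v]][i, c, sv]
          sw_sum <- 0
          for (sw in 1:4) sw_sum <- sw_sum + Pw[[c]][s, sw] * L[[w]][i, c, sw]
          arr[i, c, s] <- sv_sum * sw_sum
        }
      }
    }
    L[[u]] <- arr
  }
  per_site <- numeric(n)
  r <- tree$root
  for (i in seq_len(n)) {
    tot <- 0
    for (c in seq_len(k)) {
      for (s in 1:4) tot <- tot + model$frequencies[s] * L[[r]][i, c, s]
    }
    per_site[i] <- log(tot / k)
  }
  structure(list(loglik = sum(alignment$weights * per_site),
                 per_site = per_site),
            class = "likelihood_result")
}

#' Simulation configuration
#'
#' @param n_sites Number of alignment columns to simulate.
#' @param model A [subst_model()] (root states drawn from its stationary
#'   frequencies; sites evolve edge-wise under its transition matrices, with
#'   a rate category drawn per site).
#' @param gap_fraction,ambiguity_fraction Per-character probabilities, in
#'   `[0, 1]`, of masking a simulated base as a gap (mask 15) or as a random
#'   IUPAC ambiguity containing the true base. Gaps are injected after
#'   substitution simulation (masking, not a fifth state).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_sites, model = subst_model("JC"),
                       gap_fraction = 0, ambiguity_fraction = 0, seed = 1L) {
  stopifnot(n_sites >= 1,
            gap_fraction >= 0, gap_fraction <= 1,
            ambiguity_fraction >= 0, ambiguity_fraction <= 1)
  structure(list(n_sites = as.integer(n_sites), model = model,
                 gap_fraction = gap_fraction,
                 ambiguity_fraction = ambiguity_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate a DNA alignment along a rooted tree
#'
#' Root states are drawn from the model's stationary frequencies; each site
#' draws one rate category and its states evolve independently down every
#' edge via [transition_matrix()]. Gaps and ambiguities are then injected
#' i.i.d. per tip character at the configured rates.
#'
#' @param cfg A [sim_config()].
#' @param tree A `tree_view`.
#' @return A [plf_alignment()] over the tree's tip labels.
#' @export
simulate_alignment <- function(cfg, tree) {
  stopifnot(inherits(cfg, "sim_config"), inherits(tree, "tree_view"))
  model <- cfg$model
  n <- cfg$n_sites
  k <- model$n_categories
  .with_seed(cfg$seed, {
    cat_of_site <- sample.int(k, n, replace = TRUE)
    states <- vector("list", tree$n_nodes)
    states[[tree$root]] <- sample.int(4L, n, replace = TRUE,
                                      prob = model$frequencies)
    # preorder = reversed postorder, root first
    for (u in c(tree$root, rev(setdiff(tree$postorder, tree$root)))) {
      for (slot in 1:2) {
        ch <- tree$children[u, slot]
        t_edge <- tree$brlen[u, slot]
        P <- lapply(model$category_rates, function(r)
          transition_matrix(model, t_edge, r))
        child <- integer(n)
        for (c in seq_len(k)) {
          for (s in 1:4) {
            idx <- which(cat_of_site == c & states[[u]] == s)
            if (length(idx)) {
              child[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                       prob = P[[c]][s, ])
            }
          }
        }
        states[[ch]] <- child
      }
    }
    data <- matrix(0L, nrow = tree$m, ncol = n,
                   dimnames = list(tree$tip_labels, NULL))
    onehot <- c(1L, 2L, 4L, 8L)
    for (tip in seq_len(tree$m)) {
      mask <- onehot[states[[tip]]]
      amb <- stats::runif(n) < cfg$ambiguity_fraction
      if (any(amb)) {
        extra <- sample.int(15L, sum(amb), replace = TRUE)
        mask[amb] <- bitwOr(mask[amb], extra)
      }
      gap <- stats::runif(n) < cfg$gap_fraction
      mask[gap] <- 15L
      data[tip, ] <- mask
    }
    plf_alignment(data, taxa = tree$tip_labels)
  })
}
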