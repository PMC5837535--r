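# GTR substitution model with discrete-Gamma rate heterogeneity.
# State order throughout: A, C, G, T. Exchangeability order: AC, AG, AT,
# CG, CT, GT.

#' Discrete-Gamma category rates (mean of equal-probability quantile bins)
#'
#' The Gamma(alpha, alpha) rate distribution (mean 1) is split into `k`
#' equal-probability bins; each category rate is the mean of its bin, so the
#' category rates always average to exactly 1.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param k Number of categories (>= 1).
#' @return Numeric vector of `k` rate multipliers with mean 1.
#' @export
discretize_gamma <- function(alpha, k) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(1)
  qb <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha,
                      rate = alpha)
  # E[X | bin] * P(bin) for X ~ Gamma(a, a): uses the Gamma(a+1, a) cdf
  cum <- stats::pgamma(qb, shape = alpha + 1, rate = alpha)
  rates <- diff(cum) * k
  rates / mean(rates)  # guard against last-digit drift; mean is 1 analytically
}

#' Construct a substitution model
#'
#' @param spec Model string: `"JC"` (equal frequencies and exchangeabilities,
#'   one rate category) or `"GTR+G<k>"` / `"GTR"` (general time-reversible,
#'   optionally with `k` discrete Gamma categories, default 4).
#' @param frequencies Base frequencies (A, C, G, T); must sum to 1.
#' @param rates Six exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param alpha Gamma shape parameter (used when `spec` includes `+G`).
#' @param n_categories Overrides the category count from `spec`.
#' @return A `subst_model` with fields `frequencies`, `rates`, `alpha`,
#'   `n_categories`, `category_rates` and the eigen-system of the normalised
#'   generator.
#' @export
subst_model <- function(spec = "JC", frequencies = NULL, rates = NULL,
                        alpha = 1, n_categories = NULL) {
  spec <- toupper(spec)
  base <- sub("\\+.*$", "", spec)
  if (!base %in% c("JC", "GTR")) stop("unknown model '", spec, "'")
  k <- 1L
  if (grepl("\\+G", spec)) {
    kg <- sub("^.*\\+G", "", spec)
    k <- if (nzchar(kg)) as.integer(kg) else 4L
  }
  if (!is.null(n_categories)) k <- as.integer(n_categories)
  if (base == "JC") {
    if (is.null(frequencies)) frequencies <- rep(0.25, 4)
    if (is.null(rates)) rates <- rep(1, 6)
  } else {
    if (is.null(frequencies)) frequencies <- rep(0.25, 4)
    if (is.null(rates)) rates <- rep(1, 6)
  }
  frequencies <- as.numeric(frequencies)
  rates <- as.numeric(rates)
  if (length(frequencies) != 4L || any(frequencies <= 0) ||
      abs(sum(frequencies) - 1) > 1e-12) {
    stop("frequencies must be 4 positive values summing to 1")
  }
  if (length(rates) != 6L || any(rates < 0)) {
    stop("rates must be 6 non-negative exchangeabilities")
  }
  category_rates <- if (k == 1L) 1 else discretize_gamma(alpha, k)

  # pi-weighted GTR generator, normalised to one expected substitution per
  # unit branch length, then eigendecomposed through its symmetrisation.
  Q <- matrix(0, 4, 4)
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (e in 1:6) {
    i <- idx[e, 1]; j <- idx[e, 2]
    Q[i, j] <- rates[e] * frequencies[j]
    Q[j, i] <- rates[e] * frequencies[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(frequencies * diag(Q))
  if (mu <= 0) stop("degenerate model: zero total substitution rate")
  Q <- Q / mu
  sq <- sqrt(frequencies)
  S <- diag(sq) %*% Q %*% diag(1 / sq)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  structure(list(frequencies = frequencies, rates = rates, alpha = alpha,
                 n_categories = k, category_rates = category_rates,
                 eigenvalues = es$values,
                 U = diag(1 / sq) %*% es$vectors,
                 Uinv = t(es$vectors) %*% diag(sq)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("subst_model: pi = (", paste(signif(x$frequencies, 4), collapse = ", "),
      "), ", x$n_categories, " rate categories\n", sep = "")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' @param model A [subst_model()].
#' @param t Branch length (expected substitutions per site), >= 0.
#' @param r Rate-category multiplier, >= 0.
#' @return A 4x4 row-stochastic matrix; the identity when `t * r == 0`.
#' @export
transition_matrix <- function(model, t, r = 1) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  if (!is.finite(r) || r < 0) stop("rate multiplier must be finite and >= 0")
  if (t * r == 0) return(diag(4))
  P <- model$U %*% (exp(model$eigenvalues * t * r) * model$Uinv)
  P[P < 0] <- 0
  P
}
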