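test_that("tip CLVs mirror the encoded state bits", {
  expect_equal(tip_clv(1L), c(1, 0, 0, 0))
  expect_equal(tip_clv(5L), c(1, 0, 1, 0))
  expect_equal(tip_clv(15L), c(1, 1, 1, 1))
  for (x in 1:15) {
    expect_equal(sum(tip_clv(x)), sum(bitwAnd(x, c(1L, 2L, 4L, 8L)) > 0))
  }
})

test_that("inner CLV combination obeys its algebraic special cases", {
  k <- 2; n <- 3
  arr <- function(vals) array(vals, dim = c(4, k, n))
  set.seed(4)
  a <- arr(runif(4 * k * n)); b <- arr(runif(4 * k * n))
  I <- replicate(k, diag(4), simplify = FALSE)
  # zero-length branches (P = I): elementwise product of the children
  expect_equal(inner_clv(a, b, I, I), a * b)
  # two all-ones children (gap tips) against stochastic P: all ones
  m <- gtr_g4()
  P <- lapply(c(0.6, 1.7), function(r) transition_matrix(m, 0.2, r))
  ones <- arr(rep(1, 4 * k * n))
  expect_equal(inner_clv(ones, ones, P, P), ones, tolerance = 1e-12)
})

test_that("degenerate likelihoods take their forced values", {
  jc <- subst_model("JC")
  two <- plf_alignment(rbind(t1 = "A", t2 = "A"))
  tree0 <- parse_newick("(t1:0,t2:0);")
  res <- likelihood_rooted(tree0, two, jc)
  expect_equal(exp(res$per_site), 0.25, tolerance = 1e-14)

  gaps <- plf_alignment(rbind(t1 = "-", t2 = "-", t3 = "-"),
                        taxa = c("t1", "t2", "t3"))
  tr <- parse_newick("((t1:0.1,t2:0.2):0.1,t3:0.3);")
  tr <- root_at_terminal_edge(tr, "t1")
  expect_equal(likelihood_rooted(tr, gaps, jc)$loglik, 0, tolerance = 1e-12)
})

test_that("pruning matches the scalar oracle and honours weights/aliasing", {
  for (seed in c(101, 102, 103, 104, 105)) {
    inst <- random_instance(seed, m = 6)
    ref <- likelihood_rooted(inst$tree, inst$aln, inst$model)
    orc <- scalar_plf_oracle(inst$tree, inst$aln, inst$model)
    expect_equal(ref$loglik, orc$loglik, tolerance = 1e-10)
    expect_equal(ref$loglik, sum(inst$aln$weights * ref$per_site),
                 tolerance = 1e-10)
    comp <- compress_patterns(inst$aln)
    expect_equal(likelihood_rooted(inst$tree, comp, inst$model)$loglik,
                 ref$loglik, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to rooting and edge of evaluation", {
  inst <- random_instance(7, m = 5, n = 20)
  ut <- as_unrooted(inst$tree)
  lls <- vapply(ut$tip_labels, function(tx) {
    likelihood_rooted(root_at_terminal_edge(ut, tx), inst$aln,
                      inst$model)$loglik
  }, 0)
  expect_lt(diff(range(lls)), 1e-8 * abs(mean(lls)))
  for (e in seq_len(nrow(ut$edges))) {
    le <- likelihood_edge(ut, ut$edges[e, 1], ut$edges[e, 2], inst$aln,
                          inst$model)
    expect_equal(le$loglik, lls[[1]], tolerance = 1e-10)
  }
})

test_that("underflow rescaling is transparent and catches deep trees", {
  inst <- random_instance(13, m = 8, n = 15)
  on_ <- likelihood_rooted(inst$tree, inst$aln, inst$model, scaling = TRUE)
  off <- likelihood_rooted(inst$tree, inst$aln, inst$model, scaling = FALSE)
  expect_equal(on_$loglik, off$loglik, tolerance = 1e-12)

  # long caterpillar with long branches underflows without scaling
  m <- 800
  labs <- paste0("t", seq_len(m))
  nwk <- paste0(paste(rep("(", m - 1), collapse = ""), labs[1], ":1,",
                paste(labs[-1], collapse = ":1):1,"), ":1);")
  deep <- parse_newick(nwk)
  aln <- plf_alignment(matrix(rep(c(1L, 2L, 4L, 8L), length.out = m), m, 1),
                       taxa = deep$tip_labels)
  jc <- subst_model("JC")
  scaled <- likelihood_rooted(deep, aln, jc, scaling = TRUE)
  expect_true(is.finite(scaled$loglik))
  expect_error(likelihood_rooted(deep, aln, jc, scaling = FALSE),
               "underflow")
})

test_that("likelihood agrees with an independent implementation (phangorn)", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  phy <- ape::rtree(6)
  tree <- parse_newick(ape::write.tree(phy))
  mod <- gtr_g4()
  aln <- simulate_alignment(sim_config(30, mod, seed = 2), tree)
  ll <- likelihood_rooted(tree, aln, mod)$loglik
  chars <- matrix(c("a", "c", "g", "t")[apply(aln$data, c(1, 2),
                                              match, c(1L, 2L, 4L, 8L))],
                  nrow = nrow(aln$data), dimnames = list(aln$taxa, NULL))
  fit <- phangorn::pml(phy, phangorn::phyDat(chars, type = "DNA"),
                       bf = mod$frequencies, Q = mod$rates,
                       shape = mod$alpha, k = 4)
  expect_equal(ll, fit$logLik, tolerance = 1e-10)
})
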