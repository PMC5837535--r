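test_that("tau is bijective on its declared domain", {
  expect_equal(tau(1L, 1L, 16L), 1L)
  expect_equal(tau(16L, 16L, 16L), 256L)
  grid <- expand.grid(a = 1:16, b = 1:16)
  vals <- tau(grid$a, grid$b, 16L)
  expect_equal(sort(vals), 1:256)
})

test_that("cherry identifiers group equal tip pairs, densely numbered", {
  aln <- fig1_alignment()
  res <- assign_identifiers_cherry(aln$data[1, ], aln$data[2, ])
  expect_equal(res$phi, c(1L, 1L, 2L, 2L, 1L))
  expect_equal(res$maxid, 2L)

  same <- assign_identifiers_cherry(rep(1L, 7), rep(2L, 7))
  expect_equal(same$phi, rep(1L, 7))

  distinct <- assign_identifiers_cherry(c(1L, 1L, 2L), c(1L, 2L, 1L))
  expect_equal(distinct$phi, 1:3)
})

test_that("table-based assignment finds repeats and falls back on the bound", {
  aln <- fig1_alignment()
  tab <- new_repeat_table(1e4)
  w <- assign_identifiers_cherry(aln$data[1, ], aln$data[2, ])
  v <- assign_identifiers_cherry(aln$data[3, ], aln$data[4, ])
  u <- assign_identifiers_inner(w$phi, w$maxid, v$phi, v$maxid, tab)
  expect_equal(u$phi[2], u$phi[5])               # sites 2 and 5 repeat at u
  expect_equal(anyDuplicated(u$phi[-5]), 0L)     # all others distinct
  expect_equal(u$maxid, 4L)

  # all-distinct children identifiers stay distinct at the parent
  ad <- assign_identifiers_inner(1:6, 6L, rep(1L, 6), 1L, new_repeat_table(100))
  expect_equal(ad$phi, 1:6)

  fb <- assign_identifiers_inner(w$phi, w$maxid, v$phi, v$maxid,
                                 new_repeat_table(1))
  expect_true(fb$fallback)
  expect_equal(fb$phi, 1:5)
  expect_equal(fb$maxid, 5L)
})

test_that("the cherry tau path and the table path agree", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    xv <- sample(1:15, n, replace = TRUE)
    xw <- sample(1:15, n, replace = TRUE)
    a <- assign_identifiers_cherry(xv, xw)
    b <- assign_identifiers_inner(xv, max(xv), xw, max(xw),
                                  new_repeat_table(Inf))
    expect_equal(a$phi, b$phi)
    expect_equal(a$maxid, b$maxid)
  }
})

test_that("the worked example needs 10 CLV computations instead of 15", {
  aln <- fig1_alignment()
  tree <- fig1_tree()
  nd <- fig1_nodes(tree)
  mod <- gtr_g4()
  r <- repeats_full_traversal(tree, aln, mod, tsize = Inf)
  expect_equal(r$maxid[nd$w], 2L)
  expect_equal(r$maxid[nd$v], 4L)
  expect_equal(r$maxid[nd$u], 4L)
  expect_equal(r$clv_computations, 10L)  # vs 3 nodes x 5 sites = 15 plain
  expect_equal(r$ids[[nd$w]], c(1L, 1L, 2L, 2L, 1L))
  expect_equal(r$ids[[nd$v]], c(1L, 2L, 3L, 4L, 2L))
  expect_equal(r$ids[[nd$u]], c(1L, 2L, 3L, 4L, 2L))

  expect_equal(r$result$loglik, likelihood_rooted(tree, aln, mod)$loglik,
               tolerance = 1e-10)
  r0 <- repeats_full_traversal(tree, aln, mod, tsize = 0)
  expect_equal(sum(r0$counts), 15L)
  expect_equal(r0$result$loglik, r$result$loglik, tolerance = 1e-12)
  expect_equal(repeat_fraction(tree, aln), 100 * 5 / 15, tolerance = 1e-12)
})

test_that("identifier maps satisfy growth, root-aliasing and count bounds", {
  for (seed in c(301, 302, 303, 304, 305, 306)) {
    inst <- random_instance(seed)
    r <- repeats_full_traversal(inst$tree, inst$aln, inst$model, tsize = Inf)
    tree <- inst$tree
    n <- ncol(inst$aln$data)
    for (u in tree$postorder) {
      v <- tree$children[u, 1]; w <- tree$children[u, 2]
      # monotone growth: children classes refine, capped by the pair product
      expect_gte(r$maxid[u], max(r$maxid[v] * (v > tree$m),
                                 r$maxid[w] * (w > tree$m), 1L))
      expect_lte(r$maxid[u], min(n, r$maxid[v] * r$maxid[w]))
      # identifiers are a contiguous range in first-occurrence order
      phi <- r$ids[[u]]
      expect_equal(unique(phi), seq_len(r$maxid[u]))
    }
    # root classes = distinct full columns (aliasing at the root)
    expect_equal(r$maxid[tree$root],
                 ncol(compress_patterns(inst$aln)$data))
    expect_lte(sum(r$counts), n * (tree$m - 1L))
  }
})

test_that("repeat fraction hits its closed-form extremes", {
  one_col <- plf_alignment(matrix(rep(c(1L, 2L, 4L, 8L, 2L), 6), 5, 6),
                           taxa = paste0("t", 1:5))
  set.seed(77)
  tr <- parse_newick(ape::write.tree(ape::rtree(5)))
  tr$tip_labels <- paste0("t", 1:5)
  expect_equal(repeat_fraction(tr, one_col), 100 * (6 - 1) / 6,
               tolerance = 1e-12)

  # columns distinct at every node: one taxon distinguishes all sites
  distinct <- plf_alignment(rbind(c(1L, 2L, 4L), c(2L, 4L, 8L),
                                  c(4L, 8L, 1L), c(8L, 1L, 2L)),
                            taxa = paste0("t", 1:4))
  tr4 <- fig1_tree()
  distinct$taxa <- tr4$tip_labels
  rownames(distinct$data) <- tr4$tip_labels
  expect_equal(repeat_fraction(tr4, distinct), 0)
})

test_that("SRCT caches identifiers across model changes; SRDT recomputes", {
  inst <- random_instance(41, m = 8, n = 30)
  r1 <- repeats_full_traversal(inst$tree, inst$aln, inst$model, mode = "SRCT")
  mod2 <- gtr_g4(alpha = 1.4)
  r2 <- repeats_full_traversal(NULL, NULL, mod2, mode = "SRCT",
                               engine = r1$engine)
  expect_identical(r1$ids, r2$ids)
  fresh <- repeats_full_traversal(inst$tree, inst$aln, mod2)
  expect_equal(r2$result$loglik, fresh$result$loglik, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r1$result$loglik, r2$result$loglik)))
  # SRDT/SRCT agree on a fixed topology
  expect_identical(fresh$ids, r2$ids)
  expect_equal(fresh$result$loglik, r2$result$loglik, tolerance = 1e-12)

  other <- random_instance(42, m = 8, n = 30)$tree
  expect_error(repeats_full_traversal(other, NULL, mod2, mode = "SRCT",
                                      engine = r1$engine), "topology")
})

test_that("the lookup buffer is safely reused across traversals (clean list)", {
  inst <- random_instance(55, m = 10, n = 40)
  eng <- NULL
  ref <- repeats_full_traversal(inst$tree, inst$aln, inst$model, tsize = Inf)
  r1 <- repeats_full_traversal(inst$tree, inst$aln, inst$model, tsize = Inf,
                               mode = "SRDT")
  # second traversal on the same engine re-mints every identifier through a
  # buffer full of stale entries
  r2 <- repeats_full_traversal(inst$tree, inst$aln, inst$model, tsize = Inf,
                               mode = "SRDT", engine = r1$engine)
  expect_identical(r2$ids, ref$ids)
  expect_equal(r2$result$loglik, ref$result$loglik, tolerance = 1e-12)
})

test_that("partial updates reproduce full recomputation", {
  inst <- random_instance(61, m = 20, n = 60)
  mod <- inst$model
  r <- repeats_full_traversal(inst$tree, inst$aln, mod)
  eng <- r$engine

  # empty dirty set: unchanged result, zero CLV computations
  empty <- structure(list(nodes = integer(0), postorder = integer(0)),
                     class = "dirty_set")
  expect_equal(partial_update(eng, empty, mod)$loglik, r$result$loglik)
  expect_equal(eng$last_ops, 0L)

  # all inner nodes: identical to a full traversal
  all_d <- mark_dirty(inst$tree, inst$tree$postorder)
  expect_equal(partial_update(eng, all_d, mod)$loglik, r$result$loglik,
               tolerance = 1e-12)

  # branch-length perturbations under random dirty walks
  set.seed(600)
  for (i in 1:5) {
    d <- sample_dirty_walk(inst$tree, 0.95)
    tree2 <- eng$tree
    for (u in d$nodes) tree2$brlen[u, ] <- tree2$brlen[u, ] * runif(2, 0.5, 1.5)
    pu <- partial_update(eng, d, mod, tree = tree2)
    full <- repeats_full_traversal(tree2, inst$aln, mod)$result
    expect_equal(pu$loglik, full$loglik, tolerance = 1e-10)
  }

  not_closed <- structure(list(nodes = inst$tree$postorder[1],
                               postorder = inst$tree$postorder[1]),
                          class = "dirty_set")
  expect_error(partial_update(eng, not_closed, mod), "upward-closed")
})

test_that("memory report follows the standard footprint formula", {
  est <- memory_estimate(4, 5, k = 4)
  expect_equal(est$uncompressed_bytes, 8 * 4 * 4 * (4 - 2) * 5)  # 1280
  expect_equal(est$clv_to_identifier_value_ratio, 16)

  inst <- random_instance(71, m = 9, n = 40)
  r <- repeats_full_traversal(inst$tree, inst$aln, inst$model, tsize = Inf)
  non_root <- setdiff(inst$tree$postorder, inst$tree$root)
  est2 <- memory_estimate(inst$tree$m, ncol(inst$aln$data),
                          maxid = r$maxid[non_root],
                          k = inst$model$n_categories,
                          table_entries = r$table_entries)
  expect_lte(est2$compressed_bytes, est2$uncompressed_bytes)
})
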