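# Shared fixtures: the four-taxon worked example and a seeded random
# (tree, alignment, model) instance generator.

fig1_alignment <- function() {
  plf_alignment(rbind(t1 = strsplit("AACCA", "")[[1]],
                      t2 = strsplit("CCGGC", "")[[1]],
                      t3 = strsplit("ACGAC", "")[[1]],
                      t4 = strsplit("CTAGT", "")[[1]]))
}

# rooted: u = root, w = cherry (t1, t2), v = cherry (t3, t4); branch lengths
# are fixture choices (identifiers never depend on them)
fig1_tree <- function() {
  parse_newick("((t1:0.1,t2:0.2)w:0.3,(t3:0.15,t4:0.25)v:0.05)u;")
}

fig1_nodes <- function(tree) {
  # ids: w = parent of tips 1&2, v = parent of tips 3&4, u = root
  w <- tree$parent[match("t1", tree$tip_labels)]
  v <- tree$parent[match("t3", tree$tip_labels)]
  list(w = w, v = v, u = tree$root)
}

gtr_g4 <- function(alpha = 0.6) {
  subst_model("GTR+G4", alpha = alpha,
              frequencies = c(0.35, 0.15, 0.2, 0.3),
              rates = c(1.2, 2.5, 1.1, 0.9, 3.3, 1))
}

random_instance <- function(seed, m = NULL, n = NULL, gap = 0.15,
                            amb = 0.1, model = NULL) {
  set.seed(seed)
  if (is.null(m)) m <- sample(3:12, 1)
  if (is.null(n)) n <- sample(1:50, 1)
  tree <- parse_newick(ape::write.tree(ape::rtree(m)))
  if (is.null(model)) model <- if (seed %% 2) gtr_g4() else subst_model("JC")
  aln <- simulate_alignment(
    sim_config(n, model, gap_fraction = gap, ambiguity_fraction = amb,
               seed = seed + 1000L), tree)
  list(tree = tree, aln = aln, model = model, m = m, n = n)
}

partition_of_ids <- function(phi) {
  unname(lapply(split(seq_along(phi), phi), as.integer))
}
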