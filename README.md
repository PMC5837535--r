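# siterepeats

Phylogenetic likelihood computation that detects and exploits **site
repeats** — alignment sites that induce identical conditional likelihood
vectors at a node because their columns agree on every tip below that node.

## The problem

The phylogenetic likelihood function (PLF) dominates the cost of maximum
likelihood and Bayesian tree inference. For an alignment with `m` taxa and
`n` sites it evaluates, at every inner node `u` with children `v`, `w` and
branch lengths `b_v`, `b_w`, the Felsenstein pruning recursion

```
L_u(s, i) = [ Σ_t P(b_v)_{s,t} L_v(t, i) ] · [ Σ_t P(b_w)_{s,t} L_w(t, i) ]
```

for each state `s`, site `i`, and (under discrete-Gamma rate variation) each
rate category, with the root log-likelihood `Σ_i w_i log Σ_s π_s L_root(s, i)`.

Two sites `i`, `j` are *repeats* at node `u` when their columns restricted
to the tips below `u` are identical; then `L_u(·, i) = L_u(·, j)` and the
vector needs to be computed only once. Repeats are abundant in real
alignments — far beyond the fully identical columns removed by ordinary
site-pattern compression — and detecting them exactly at every node is
possible in linear time per node.

## The algorithm

`siterepeats` implements bottom-up repeat detection with per-node integer
**identifiers** `φ_u(i)`:

* at tips, `φ` is the encoded character (IUPAC 4-bit mask, values 1–15);
* at an inner node, two sites get the same identifier iff their child
  identifier pairs `(φ_v(i), φ_w(i))` coincide. Pairs are mapped through a
  single flat lookup table indexed by `d = (φ_v − 1)·maxid_w + φ_w`, with an
  epoch-stamped *clean list* so the table never needs clearing between nodes;
* when a node's index space `maxid_v · maxid_w` exceeds the user-set table
  bound (default `5·10⁷` entries ≈ 200 MB at 4 bytes/entry), the node falls
  back to unique identifiers `1..n` and its ancestors do too — correctness is
  preserved, only the saving is lost at those nodes.

Conditional likelihood vectors are stored **compressed**: node `u` keeps
`maxid_u ≤ n` vectors instead of `n`, and the modified recursion fetches the
children's entries via their identifiers. Per-class scaling (threshold
`2⁻²⁵⁶`) protects against numerical underflow on large trees.

Two operating modes mirror the two ways inference tools call the PLF:

* **SRDT** (dynamic topology): identifiers are recomputed at every
  traversal — safe under topology moves;
* **SRCT** (constant topology): identifiers are computed once and reused
  across model and branch-length changes, as in divergence-time estimation.

`partial_update()` recomputes only an upward-closed *dirty set* of nodes
after local branch-length changes.

## Worked example

The four-taxon alignment below (tree `((t1,t2),(t3,t4))`) has 5 sites.

```r
library(siterepeats)
aln  <- plf_alignment(rbind(t1 = strsplit("AACCA", "")[[1]],
                            t2 = strsplit("CCGGC", "")[[1]],
                            t3 = strsplit("ACGAC", "")[[1]],
                            t4 = strsplit("CTAGT", "")[[1]]))
tree <- parse_newick("((t1:0.1,t2:0.2):0.3,(t3:0.15,t4:0.25):0.05);")
r <- repeats_full_traversal(tree, aln, subst_model("JC"))
r$ids[[tree$children[tree$root, 1]]]  # 1 1 2 2 1 : sites {1,2,5} repeat
r$clv_computations                    # 10 instead of 5 sites x 3 nodes = 15
repeat_fraction(tree, aln)            # 33.33 (% of inner CLVs saved)
r$result$loglik                       # -37.82626
```

Sites 1, 2 and 5 all read `(A, C)` at the `(t1, t2)` cherry, so that node
computes 2 vectors instead of 5; overall 10 of 15 inner-node vector
computations remain. With the table bound forced to 0 every node falls back
and exactly 15 are computed — same log-likelihood either way.

Command-line use (likelihood / stats / simulate):

```sh
Rscript inst/cli/siterepeats.R likelihood --tree t.nwk --msa a.fasta \
    --model GTR+G4 --alpha 0.5 --mode srdt --out report.json
Rscript inst/cli/siterepeats.R stats --tree t.nwk --msa a.fasta
Rscript inst/cli/siterepeats.R simulate --prefix sim --taxa 20 --sites 500 --seed 7
```

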