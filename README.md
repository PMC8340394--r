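# dtlor

Maximum-parsimony reconciliation of a rooted gene tree against a rooted
species tree under the **DTLOR** model: **D**uplication, **T**ransfer,
**L**oss, **O**rigin and **R**earrangement.

Standard DTL reconciliation assumes every gene lineage lives inside the
sampled species tree. In clades of closely related microbes that assumption
fails in two ways: gene families enter the clade by horizontal transfer
from unsampled lineages, and genes move between *syntenic regions* (integer
labels summarizing a gene's genomic neighborhood). DTLOR adds an *origin*
event for entry from outside and a *rearrangement* event for a change of
syntenic region along a gene-tree edge. A reconciliation is a pair of
mappings $(\Phi, \Gamma)$: $\Phi$ sends each gene vertex to a species
vertex or the outside location $N$, $\Gamma$ sends it to an actual region
or the unknown region $*$ (with $\Phi(g)=N \iff \Gamma(g)=*$). Given
nonnegative costs $D, T, L, O, R$ (defaults $1,1,1,2,2$), the package finds
mappings minimizing the total induced-event cost

$$D\,n_{dup} + T\,n_{trans} + L\,n_{loss} + O\,n_{orig} + R\,n_{rearr},$$

with speciations free. For binary gene trees the species and synteny
mappings decouple inside origin subtrees and are solved by two dynamic
programs in `O(|G||S| + |G||L|)` time, then combined; for multifurcating
gene trees a fixed-parameter joint program evaluates every binary
resolution of each polytomy ($(2k-3)!!$ for arity $k$) on ℓ-indexed tables.
The package also counts co-optimal reconciliations exactly (binary case),
reconstructs one reconciliation deterministically, ships brute-force
reference implementations, and generates synthetic instances and
forward-simulated gene histories.

Intended users: microbial comparative genomicists postprocessing gene
families (e.g. from a pangenome or genomic-island pipeline) who need per-
family event histories, and methods developers who want a verified,
scriptable DTLOR solver.

## Worked example

```r
library(dtlor)

S <- parse_newick("((a,b)x,c)r;")            # species tree
G <- parse_newick("((ga,gb)u,gc)v;")         # gene tree
inst <- dtlor_instance(
  S, G,
  phi   = c(ga = "a", gb = "b", gc = "c"),   # gene leaf -> species leaf
  gamma = c(ga = 1,  gb = 1,  gc = 2),       # gene leaf -> syntenic region
  costs = dtlor_costs())                     # D,T,L,O,R = 1,1,1,2,2

sol <- dtlor_solve(inst)
sol
#> dtlor_solution: optimal cost 4 (3 co-optimal reconciliation(s))

rec <- dtlor_traceback(sol)
rec
#> dtlor_reconciliation: cost 4 (speciation:1, duplication:0, transfer:0,
#>   loss:0, origin:2, rearrangement:0)
rec$phi
#>  ga  gb  gc   v   u
#> "a" "b" "c" "N" "x"
```

The optimum of 4 is achieved three ways: two separate origins at `u` and
`gc` (the gene root stays outside the sampled tree, `phi["v"] = "N"`), or
one origin at the root with a single rearrangement — on the `gc` edge if
the root region is 1, on the edge to `u` if it is 2. The deterministic
traceback prefers unknown-region solutions at ties and reports the first;
`count_mprs(sol)` returns 3.

Multifurcating gene trees go through the polytomy solver, which also
returns the optimal binary resolution:

```r
tri <- dtlor_instance(S, parse_newick("(g1,g2,g3)v;"),
                      phi = c(g1 = "a", g2 = "b", g3 = "c"),
                      gamma = c(g1 = 1, g2 = 1, g3 = 1))
nb <- solve_nonbinary(tri)
nb$opt                      # 2: one origin, the tree resolves isomorphically
write_newick(nb$resolved)   # "((g1,g2)v#1,g3)v;"
```

A thin command-line wrapper is installed as `exec/dtlor`:

```sh
dtlor reconcile --species S.nwk --gene G.nwk --map map.tsv --synteny syn.tsv \
      -D 1 -T 1 -L 1 -O 2 -R 2 --count --out rec.json
dtlor simulate --seed 7 --species-leaves 6 --out-prefix sim/run1
```

Association tables are two-column TSV (gene leaf, value), `#` comments
allowed. Reports are JSON with a stable schema and byte-identical output
for identical input.

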