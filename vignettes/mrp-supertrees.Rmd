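---
title: "Building MRP supertrees from curated source phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building MRP supertrees from curated source phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrptree)
```

## The problem

A supertree synthesises one large phylogeny from many published source trees
that each cover only a fraction of the taxa of interest. Large literature-mined
compilations — hundreds to a thousand trees spanning thousands of species, as
in comprehensive bird supertrees — cannot be analysed from primary character
data, because the underlying matrices are heterogeneous or unavailable.
Matrix Representation with Parsimony (MRP) sidesteps this: each source-tree
clade becomes one binary pseudo-character, the pseudo-characters are
concatenated, and the combined matrix is analysed under parsimony. mrptree
implements that pipeline end to end — curation of the raw tree collection,
Baum–Ragan coding, parsimony search, consensus/agreement summarisation, and
post-hoc diagnostics — together with a synthetic source-tree generator that
provides ground truth for every stage.

## The model: Baum–Ragan coding and parsimony

For a source tree on leaf set $L$ inside a taxon universe $U$, every internal
node (except the root, whose all-ones column is uninformative) contributes one
column: taxa subtended by the node are scored 1, the tree's other taxa 0, and
taxa in $U \setminus L$ are scored `?`. A hypothetical outgroup, the reserved
taxon `MRP_Outgroup`, is scored 0 in every column and roots the analysis; the
supertree is read off the optimal trees after re-rooting on it and removing
it. Rooting is assumed throughout: the coding is defined on rooted clades, so
unrooted inputs are treated as rooted at their file-given basal node.

Tree length is the minimum number of 0↔1 changes summed over columns. We
compute it with the two-state Sankoff dynamic programme
($c_s(v) = \sum_{u \in \mathrm{child}(v)} \min(c_s(u), c_{1-s}(u) + 1)$),
which coincides with Fitch on bifurcating nodes and handles polytomies exactly
(the Hartigan generalisation); `?` enters as the free state set $\{0,1\}$. The
recursion is vectorised over columns in C++. Its correctness is tested against
an independent oracle that enumerates every assignment of states to internal
nodes and missing-state leaves.

## Curation protocol

Literature-mined trees need standardising before they can be combined. The
curation stage applies, in order:

1. **Name standardisation** — rename/delete rules from a plain-text
   substitution file (`old = new`, empty right side deletes) fix synonyms,
   misspellings, and excluded taxa. If two leaves collapse onto one name, the
   copy closest to the root is kept (the deeper copy is more often a
   secondary, misplaced occurrence) and a warning is logged.
2. **Paraphyletic genus-level occurrences** — a bare genus label co-occurring
   with congeneric species is placed by enumerating all positions
   (`permute_paraphyletic`), summarising the non-identical permutations with a
   mini-supertree (MRP over the permutations; exhaustive search up to 9
   ingroup taxa, heuristic above), and leaving a single placeholder.
   Genuinely scattered occurrences therefore end as a polytomy: the method
   reports ambiguity rather than inventing a position.
3. **Higher-taxon substitution** — expand rules replace family/vernacular
   leaves by a polytomy of their constituent taxa, *restricted to taxa already
   in the dataset* so substitutions can never inflate the taxon set;
   singletons rename, empty intersections prune with a warning.
4. **Genus expansion** — leaves without an epithet become polytomies of the
   genus members present in the dataset; unknown genera are flagged for a
   manual rule.
5. **Non-independence** — records with identical character-tag sets and
   identical taxa are flagged for manual combination (a mini-supertree of the
   pair is the provided combiner); when one taxon set is a proper subset of
   the other, the less comprehensive record is dropped. Character-tag equality
   is set equality on lower-cased tags; anything finer is not recoverable from
   metadata.
6. **Overlap check** — the dataset must form a single connected component in
   the graph whose edges join records sharing at least two taxa; otherwise the
   relative rooting of the components is unidentifiable and the run aborts,
   naming the components.

A final report-only validation cross-checks leaves against a canonical name
list, rules against the dataset ("problem taxa"), and metadata ids against
tree ids.

A poorly resolved, taxonomically complete *seed tree* may be included as an
ordinary record tagged `taxonomy`. It only improves overlap; it has no
constraint semantics, and because it is mostly unresolved it contributes few
columns and cannot override denser signal.

## Search

The search space is rooted binary trees with the outgroup constrained basal
(equivalent to unrooted search plus outgroup rooting, since parsimony length
is invariant to root placement). Each random start builds a tree by stepwise
addition — taxa in seeded random order, each inserted where length grows
least — then hill-climbs over NNI and SPR rearrangements, accepting the first
strictly improving neighbour per sweep. At a local optimum, equal-length
neighbours are explored breadth-first up to a configurable plateau width
(default 64) to collect most-parsimonious trees; plateau truncation can only
make the strict consensus *more* resolved, never remove a cluster that all
optimal trees share, so recovery statistics are conservative in the other
direction and MPT counts are reported as search-dependent, not normative.
Ties are broken by fixed enumeration order and trees are deduplicated by
canonical Newick (children ordered by smallest descendant label), so a fixed
configuration is fully deterministic. An exhaustive enumerator over all
$(2n-3)!!$ rooted ingroup topologies (up to 9 ingroup taxa) provides the
exact optimum for validation.

Defaults: 3 random starts, NNI+SPR, plateau 64, hill-climb round cap 200.
These are sized for the few-dozen-taxon datasets the synthetic conditions
use; real compilations with thousands of taxa need dedicated parsimony
software, and the package's value there is the curation, coding, and
diagnostic stages around such a search.

## Summaries and diagnostics

* **Strict consensus** — the tree whose clusters are exactly the intersection
  of the optimal trees' cluster sets (cross-checked against an independent
  consensus implementation in the tests).
* **Agreement subtree** — a taxon subset on which all trees induce identical
  restrictions, found by repeatedly deleting the taxon in the most conflicting
  rooted triplets (ties: lowest source-tree occurrence, then alphabetical).
  The result is verified against the definition before it is returned, but it
  is not guaranteed maximal; an exact maximum agreement subtree by subset
  enumeration (≤ 12 leaves) bounds it in the tests. Note that agreement is
  evaluated on *rooted* restrictions: two maximally conflicting quartets share
  only a two-taxon agreement subtree, although the unrooted intuition suggests
  three.
* **Resolution** — $100 (I - 1)/(n - 2)$ for $I$ internal nodes (root
  excluded) and $n$ leaves: 100 for a binary tree, 0 for a star. Because
  published resolution figures rarely state their denominator, the
  root-inclusive convention $100\,I/(n-1)$ is also available.
* **Novel clades** — a supertree cluster is supported by a record when its
  restriction to the record's taxa (at least two of them, and not the
  record's whole leaf set) is exactly one of the record's clusters; clades
  with no supporter are novel, and taxa whose smallest containing cluster is
  novel are counted as "placed in a novel clade". The exact-match rule is the
  strictest reading; a compatibility-based alternative (source polytomies
  merely consistent with the cluster count as support) is available behind
  `compatible = TRUE`.
* **Rogue-taxon report** — per taxon: source-tree occurrence count, number of
  distinct positions (distinct sibling sets intersected with a reference
  sample of the most frequent taxa — "variable position" needs an
  operationalisation and this is ours), fraction of occurrences inside
  polytomies, and fraction as an original-study outgroup. The report is
  diagnostic only; no taxa are removed automatically.
* **Data-availability matrix** — taxa × trees presence/absence, both margins
  sorted by frequency, with an MTX-style sparse writer and a dot-plot
  `autoplot()` method.

## The synthetic generator

`generate_dataset()` emulates the structure of a literature-mined compilation
with known ground truth: a binary "true" tree built by two-level random
sequential joining (a genus-level topology whose leaves are replaced by
species subtrees, so genera are clades and genus-level noise is meaningful);
overlapping source trees as restrictions of the true tree to chained random
subsets (consecutive subsets share at least two taxa, so connectivity holds
by construction rather than by rejection sampling); optional conflict as
random NNI moves; and optional curation noise — synonym renames, higher-taxon
collapses of unstructured clades, bare-genus relabellings next to a congener,
and cloned records with pruned taxon sets as planted non-independent studies.
Publication years are drawn skewed towards recent decades and character tags
from a pool of loci and data types, to exercise the metadata paths.

Noise is planted only where the generated rule files can reverse it exactly
(for example, higher-taxon collapse targets clades with no internal
resolution, whose re-expansion into a polytomy restores the original cluster
set verbatim), which is what makes the curation round-trip a sharp test.
Sequence evolution, estimation error correlated with branch length, and
fuzzy synonymy (misspellings requiring approximate matching) are *not*
emulated; a passing round-trip shows the curation machinery is lossless on
rule-described noise, not that rule files for real data are easy to write.

Default conditions: 32 taxa, 20 source trees of 8–16 leaves, no conflict, a
seed tree retaining 30% of the true tree's internal nodes, geometric genus
sizes with mean 2.5. Branch lengths are never simulated — the pipeline is
topology-only, so a birth–death model would add realism the method cannot
see.

## Numerical and design choices

* All randomness flows from explicit integer seeds through an RNG-restoring
  wrapper; no function disturbs the session RNG state.
* Canonical Newick output (children sorted by smallest descendant label)
  makes outputs diffable and equality testable as string identity.
* The scorer saturates "forbidden" costs at $2^{24}$ to avoid overflow while
  keeping integer arithmetic.
* Degenerate inputs: trees need ≥ 2 leaves; encoding a star contributes zero
  columns (logged); restriction below two surviving leaves, empty parsimony
  matrices passed to search, and outgroup name collisions are errors;
  records emptied by curation are flagged invalid and reported, not silently
  dropped.
* Columns whose cluster subtends all but one taxon of a source tree are
  retained: against the all-zero outgroup they still carry rooting signal.

## Validation at a glance

The test suite and `scripts/acceptance.R` re-derive every load-bearing claim
at runtime: scorer vs brute-force enumeration (500 cases, ≤ 8 leaves),
heuristic vs exhaustive optimum (100 matrices, 5–8 ingroup taxa), ≥ 95%
cluster recovery on 20 no-conflict replicates (24 taxa, 15 trees), exact
curation round-trips under planted noise with all duplicates detected, and
definitional validity plus MAST-boundedness of 100 agreement subtrees. These
problem sizes keep the full validation run in the low minutes on one core
while leaving the exhaustive oracles feasible; they are small-scale stand-ins,
not reproductions of published compilations.

## Known limitations

* Heuristic search at realistic supertree scale (thousands of taxa) is out of
  scope; the exhaustive oracle stops at 9 ingroup taxa and the exact MAST at
  12 leaves.
* Only standard Baum–Ragan coding is provided — no Purvis coding, weighted
  MRP, or irreversible parsimony.
* Support values (bootstrap-style or source-based) are not computed.
* The combination of identical-taxa non-independent studies is provided as a
  mini-supertree but flagged for manual review: which studies to merge is a
  judgement the software should not make alone.
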