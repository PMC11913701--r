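---
title: "OrthoQuery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OrthoQuery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

OrthoQuery answers a recurring question in comparative screening: *given a
protein I care about, which proteins in a panel of proteomes are its
putative orthologs, how similar are they, and how do they cluster?* This
vignette is the package's own account of the models it uses, the parameters
that matter, and the choices made where the design was genuinely open.

## The workflow

```{r, eval = FALSE}
library(OrthoQuery)
res <- runQueryPipeline("proteomes/", "groups.tsv", "query.fasta")
```

internally composes: header parsing → group lookup (or inference) → query
matching → progressive multiple alignment → percent identity matrix →
p-distance → neighbor joining → midpoint rooting → artifact writing. Each
stage is exported and usable on its own.

## Sequence input and the header convention

Proteome dumps from large portals label sequences with pipe-delimited
headers. Two field orders circulate in practice, so the order is a
configuration preset rather than a constant:

* `species_protein_group` (default): `source|species|protein|group`
* `species_group_protein`: `source|species|group|protein`

The parser is deliberately lenient — a header with fewer than two fields
keeps only its raw text — because real dumps contain free-form headers and
a query FASTA should never be rejected for its label. Sequences are
uppercased on read (identity counting must be case-insensitive), a trailing
`*` stop symbol is stripped (it would poison substitution-matrix lookups),
and rare/ambiguous residues (X, B, Z, U, O, J) are retained. Duplicate
headers within a file are kept, warned about, and disambiguated with an
occurrence suffix in the internal keys: silently overwriting records loses
data.

## Ortholog groups: parsing and the built-in inference

Upstream orthology engines emit one row per putative ortholog group in a
non-standardized tabular flavour. The parser is driven by a *dialect*
object (column separator, within-cell member separator, `id:score`
confidence suffix, `*` placeholder), with the default dialect matching the
common tab-separated layout: first column the group id, one column per
species. Parsed tables are tidy (one row per member) and must partition
the proteins — a protein in two groups is a validation error, because every
downstream interpretation assumes group membership is an equivalence-like
relation. Member confidences are carried but never required: the pipeline
downstream uses only membership.

When no upstream run is available, `inferGroups()` provides a small-scale
stand-in: all-vs-all global alignment, best hit per (protein, other
species) with scores normalized by the query's self-alignment score
(length-robust, bounded by 1), reciprocal-best-hit filtering at
`minScore = 0.05` (deliberately permissive — the tool's role is exploratory
screening, and a conservative threshold would silently hide candidates),
and connected components as groups, with singletons excluded. This is a
*compatible output schema, simplified inference* — it does not attempt
in-paralog expansion or the scoring internals of production orthology
engines, and the flat-file parser remains the fidelity path for real
upstream output.

## Alignment

Pairwise alignment is global Needleman–Wunsch with affine gaps over
BLOSUM62, gap open 10, gap extension 1 — the classic protein
global-alignment setting. A gap of length $L$ costs
$\mathrm{open} + (L-1)\cdot\mathrm{extend}$, and terminal gaps are
penalized like internal ones (the inputs are presumed full-length
proteins, where a dangling terminus is genuine divergence). Traceback ties
prefer the diagonal move, then a gap in the second sequence, then a gap in
the first, making alignments bit-reproducible across platforms.

Multiple alignment is classic progressive alignment: pairwise p-distances
feed a neighbor-joining guide tree, and profiles are merged bottom-up by
profile–profile global alignment, scoring a column pair as the expected
substitution score between the two columns' residue distributions (gaps
excluded from the distributions; all-gap columns removed after each
merge). No iterative refinement or HMM machinery is attempted: the
downstream contract — a percent identity matrix and a distance tree —
depends on alignment quality, not on engine identity, and a deterministic
self-contained aligner is worth more here than the last percent of
alignment accuracy.

## The percent identity matrix

For alignment rows $i, j$:

$$\mathrm{PIM}_{ij} = 100 \cdot
  \frac{\#\{\text{columns where } i \text{ and } j \text{ are identical residues}\}}
       {\#\{\text{columns where both } i \text{ and } j \text{ carry a residue}\}}$$

The *co-residue* denominator is the default because it makes identical
sequences score exactly 100 regardless of gaps induced by other rows.
Because conventions differ between tools, the denominator is a
configuration enum rather than a hidden constant: `"shorter"` (ungapped
length of the shorter sequence) and `"alignment"` (full alignment width)
are also available. Pairs with no co-residue columns score 0 with a
warning. Values are reported to one decimal place in all artifacts.

## Distances, neighbor joining, midpoint rooting

Identity converts to distance by the simple p-distance
$d = 1 - \mathrm{PIM}/100$. A Kimura-style correction for multiple
substitutions, $d = -\ln(1 - p - 0.2p^2)$, is available but off by
default: at screening-level divergences the correction changes little, and
an uncorrected default keeps the tree scale interpretable as observed
dissimilarity.

Neighbor joining is the canonical Saitou–Nei algorithm: join the pair
minimizing the Q-criterion, branch lengths from the two-point formulas,
repeat. Two numerical policies make it robust and reproducible:

* **Tie-break**: equal Q values resolve to the lowest (row, column) index
  pair, so identical inputs give bitwise-identical Newick output.
* **Negative branch lengths** (possible on non-additive input) are clamped
  to zero with the deficit transferred to the sibling edge, preserving the
  joined pair's summed length — the standard practice, and it keeps
  midpoint rooting well-defined.

The unrooted result carries a trifurcating top node. Midpoint rooting
places the root halfway along the path between the two most distant
leaves (ties broken alphabetically); if the midpoint falls exactly on an
internal node the tree is rooted there. Total branch length is conserved.
Rooting is on by default and can be disabled (`--no-midpoint-root`) for an
unrooted view.

Newick serialization always emits branch lengths (6 significant digits)
and single-quotes labels containing reserved characters — including `|`,
which the pipe-delimited label convention guarantees — so labels survive
the round trip. The parser reports character positions on malformed input.

## Query matching

How a query should be associated with a group is genuinely
under-determined, so the pipeline uses an explicit cascade and records the
mode per query:

1. **exact-sequence** — byte-identical to a member sequence;
2. **header** — equal `(species, protein)` key;
3. **best-alignment** — best global-alignment hit with percent identity ≥
   90 by default.

Exact matches must win; the alignment fallback exists for queries from
species whose proteome is not in the panel at all (the motivating use
case), which can never header-match. Unmatched queries are a reported
state, not an error. When several queries hit several groups the result is
the deduplicated union, with group provenance kept per record. A query
byte-identical to a resolved member is represented by that member's row
rather than duplicated. Species codes link to proteome files by file stem,
matching portal naming practice.

## The proteome simulator

`simulateProteomes()` exists so that every stage is testable offline with
known ground truth. It evolves one protein per family per species down a
known species tree: on each branch, indels first (per-site probability
`indelRate`, split evenly between single-residue deletion and insertion),
then substitutions — each site replaced with probability equal to the
branch length, drawing uniformly from the other 19 residues, so a branch's
expected observed divergence equals its length (verified binomially in the
tests). Identical specs give byte-identical FASTA output.

Defaults, chosen once as a realistic small screening panel: 8 species on a
fixed tree with per-branch rates 0.02–0.08 substitutions/site, 3 families,
family length 120, indel rate 0.01. For the end-to-end recovery checks the
suite instantiates the simulator at family length 300 — full-length-protein
scale, comparable to typical screening targets — because topology recovery
is a statistical property: an internal branch of rate $b$ on $L$ sites
carries $bL$ expected substitutions and is unresolvable with probability
$\approx e^{-bL}$ no matter how good the method is. At $L = 300$ every
internal branch of the default tree carries ≥ 9 expected changes and
neighbor-joining recovery of the generating topology is essentially
certain; at $L = 120$ occasional zero-substitution branches make exact
recovery a coin-flip event at the few-percent level.

What the simulator deliberately does **not** emulate: realistic amino-acid
exchange processes (WAG/LG-style rate matrices), rate heterogeneity across
sites, paralog birth–death, multi-residue indels. Passing tests therefore
demonstrate the pipeline's correctness and determinism on
uniform-replacement data, not its accuracy on real proteomes, where
alignment difficulty and orthology ambiguity are dominated by exactly the
features the simulator omits.

## Degenerate inputs and edge policies

* Single-sequence alignment requests return a one-row alignment with a
  warning, not an error.
* Fewer than 2 resolvable sequences: PIM and tree are skipped with a
  warning; the ortholog table is still written. Zero resolvable sequences
  is a hard error with diagnostic counts.
* Group members whose sequences cannot be found in the proteome directory
  are dropped with a logged warning and listed in the manifest.
* All-identical inputs (all distances 0) root at an arbitrary but
  deterministic point of the zero-length tree.

## Known limitations

* The aligner is quadratic per pair; the built-in inference is all-vs-all
  and meant for panels of tens of species, not thousands of proteomes.
* p-distance underestimates true divergence beyond ~30% dissimilarity;
  enable the Kimura option when absolute branch lengths matter.
* Reciprocal-best-hit inference cannot represent in-paralogs (two
  same-species members of one group) by construction; use a real orthology
  engine's output via the parser when paralogy matters.
* Translating species codes to binomial names is out of scope; labels stay
  in the input's nomenclature.
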