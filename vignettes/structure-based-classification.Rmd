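---
title: "Structure-based fine-grained classification of protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based fine-grained classification of protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trmsd)
```

## The method

Sequence-based phylogenetics loses resolution as homologs diverge: below
roughly 30% identity, alignment and distance estimation both become
unreliable, while protein structure is conserved far longer than sequence.
This package classifies a family of homologous proteins *by structure*,
at a resolution comparable to a sequence phylogeny, and attaches to every
cluster a support value that says how much of the alignment backs it.

The inputs are a multiple sequence alignment (MSA) of the family and one
experimental structure per sequence. The analysis works entirely in the
coordinate system of the *ungapped columns*: alignment columns with a
residue in every sequence whose representative atom (CA by default) is
resolved in every structure. For a structure $A$, let $d_A(c, c')$ denote
the Euclidean distance between its representative atoms at ungapped
columns $c$ and $c'$. These intramolecular distances are invariant to
rotation and translation, so no superposition is ever performed and the
result cannot depend on how the coordinate files are oriented.

For each ungapped column $c$, an inter-structure distance matrix is built
from a distance-RMSD (dRMSD) restricted to that column's distance set:

$$ M_c(A,B) \;=\; \sqrt{ \frac{1}{K-1} \sum_{c' \neq c}
   \big( d_A(c,c') - d_B(c,c') \big)^2 } $$

where $K$ is the number of ungapped columns. The $1/(K-1)$ normalisation
makes matrices comparable across alignments of different depth; whether
one normalises by $K$, $K-1$, or not at all does not change any tree
topology (NJ is scale-invariant), and the choice is recorded in
`run_log.json` so results are auditable.

Each of the $K$ matrices is turned into an unrooted tree with a
re-implementation of classic neighbor joining (Saitou–Nei $Q$ criterion,
standard limb-length formulas), and the $K$ trees are combined by
*strict* majority-rule consensus: a bipartition enters the consensus
exactly when it occurs in more than $K/2$ column trees. Strict majority
guarantees the retained splits are mutually compatible, so the consensus
needs no arbitration; the price is that it may contain polytomies where
no resolution reaches a majority, and the package reports the consensus
as-is rather than forcing a binary tree. Each internal edge carries the
count of supporting ungapped columns — analogous to a bootstrap value,
but over alignment positions instead of resamples.

Finally every column is scored for *discriminativeness*: the fraction of
consensus bipartitions its own tree recovers. Columns whose local
geometry varies between subfamilies drive the topology and score high
(red); structurally conserved columns score low (blue). The score is
deliberately the same bookkeeping as the supports — summing
$\text{score}_c \times |\text{splits}|$ over columns returns the total of
the support counts exactly. The per-column agreement counts are also
written out, so alternative statistics can be recomputed from the
reports.

## A worked run

```{r run}
fam <- make_family(n_clusters = 3, per_cluster = 4, n_residues = 40,
                   noise_sigma = 0.1, angle_step = 30, seed = 1)
fit <- trmsd(fam$msa, structures = fam$structures)
fit
```

```{r summary}
summary(fit)
```

```{r plot, fig.width = 6, fig.height = 5}
plot(fit)
```

The three planted clusters appear as clans (connected subtrees under some
rooting) with support counts close to $K = 40$, and the columns inside
the hinged domain score higher than the static ones.

## Design decisions

**Representative atom.** CA is the standard choice for backbone dRMSD; a
`--atom CB` option uses side-chain-facing beta carbons instead (falling
back to CA for glycine). **First model only** is read from multi-model
(NMR) files; ensembles are not averaged. **Altlocs** resolve by highest
occupancy, ties by alphabetical altloc code — an arbitrary but
deterministic rule.

**Missing coordinates gap the column globally.** A column is usable only
if *every* structure resolves it; pairwise deletion would let different
matrix entries be computed over different column sets and break
comparability across columns.

**No distance envelope.** Unlike DALI-style scores, no weighting or
cutoff is applied over the partner columns $c'$; the statistic is the
plain restricted dRMSD.

**Strict (not extended) majority.** Extended-majority consensus greedily
completes the tree with sub-majority splits; the strict rule was chosen
because its output is exactly characterised and always compatible.
Supports therefore never fall at or below $K/2$.

**NJ details.** Negative branch lengths are kept as computed (the
consensus uses topology only, so downstream results are unaffected); a
`clamp_negative` option zeroes them for display. Ties in the $Q$
criterion are broken by the smallest pair in current label order, with
freshly created nodes appended at the end — this matters only on
degenerate (exactly tied) matrices, where it makes the output
reproducible. A 2-leaf input is written as `(A:d/2,B:d/2);` so the
leaf-to-leaf path length equals the input distance; Newick cannot express
a bare edge between two leaves.

**Determinism.** The pipeline has no stochastic step; the `--seed` flag
exists only for the simulator. Consensus trees are emitted with leaves in
lexicographic order, so the output bytes are invariant even to the order
of the input records.

## What the synthetic generator emulates

Real inputs to this analysis are crystallographic or NMR structures of
one protein family whose members fall into conformational subfamilies.
The bundled generator fabricates a caricature of that situation that is
fully under control of a seed:

* an idealised alpha-helical CA trace (radius 2.3 Å, twist 100°, rise
  1.5 Å per residue, hence ~3.8 Å consecutive-CA spacing) stands in for
  the fold;
* cluster $k$ differs from the reference by a rigid hinge rotation of the
  C-terminal two thirds of the chain by $k \cdot \texttt{angle\_step}$
  degrees — a two-domain architecture with the large domain reorienting
  about a hinge point;
* every structure receives independent Gaussian coordinate noise
  (`noise_sigma`, in Å, emulating coordinate error and thermal
  variation), applied *after* the perturbation so that cluster separation
  is controlled by `angle_step` alone, and is then hidden behind a random
  rigid motion so that only superposition-free statistics can succeed;
* the MSA is the gapless identity alignment (the structures are conformers
  of one sequence); optional planted gap columns — excluded downstream by
  the ungapped-column rule — exercise the validation path.

**Hinge axes: why they are chosen the way they are.** Planting $k$
*distinct* clusters requires their conformations to sit in general
position, not along a single path in conformation space. Two failure
modes must be designed away. First, if all clusters bend about one shared
axis, the conformations are collinear and every intermediate cluster is
metrically between its neighbours — no distance-based method can recover
it as a clan, so the generator would not actually be planting separable
clusters. Second, and more subtly: residues outside the moved domain all
view a rigid rotated domain from nearly the same direction, which
collapses each column's profile to the *bend magnitude* alone — so even
random per-cluster axes fail when the bend magnitudes form a ladder
($k \cdot \texttt{angle\_step}$). The generator therefore inclines the
axis of cluster $k$ from the helix axis by the angle that keeps the
effective bend of the moving domain at `angle_step` for every cluster
(the remainder of the $k \cdot \texttt{angle\_step}$ rotation becomes an
axial twist), and spreads the bend directions 60° apart in azimuth. The
planted conformations are then pairwise roughly equidistant, every
cluster is separable in principle, and recovery becomes a fair test of
the analysis rather than of the planting. The pivot residue itself lies
on every hinge axis and does not move; the family's `perturbed_segment`
records only the columns that actually moved.

**What passing tests do and do not show.** The generator produces exact
rigid subdomain motion, isotropic noise, a gapless alignment, and equal
cluster sizes. Real families add alignment error, loops with genuine
flexibility, missing density, and unbalanced sampling — none of which the
synthetic tests exercise. Recovery of planted clusters here demonstrates
the correctness of the machinery (geometry, trees, consensus,
bookkeeping), not a guarantee about any particular real family.

## Numerical choices and degenerate inputs

Symmetry of distance matrices is asserted to $10^{-9}$ Å; the geometry is
checked against a naive double-loop oracle to $10^{-12}$ in the tests.
Analyses with fewer than two ungapped columns abort with a validation
error, as do alignments with ragged rows, duplicate identifiers, template
lists with missing files, and residue-identity mismatches between an
alignment row and its structure (the `X` wildcard, produced by unknown
residues, matches anything). All-identical structures yield all-zero
matrices; the column trees are then resolved by the deterministic
tie-break and the consensus correctly degrades to a star with no internal
edges. The default sequence cap (150) is policy rather than algorithmic
and can be raised.

Problem sizes in the test-suite were chosen to keep the default run
around ten seconds (twenty 12-structure families of 40 residues for the
recovery study; hundreds of small random instances for the oracle
checks); all of them are generated in code at run time.

## Limitations

* The alignment is consumed as given; no structure-aware realignment is
  attempted, and alignment errors propagate into the column definitions.
* Only single-chain, single-conformer coordinate sets are used per
  sequence; mmCIF files and NMR ensemble averaging are out of scope.
* Strict majority consensus can leave polytomies; no branch lengths are
  estimated on the consensus.
* The discriminativeness statistic is one defensible choice (consensus
  split recovery); the reports include raw agreement counts so other
  statistics can be derived.
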