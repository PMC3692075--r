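# trmsd — structure-based fine-grained classification of protein families

Sequence phylogenies lose resolution once homologs drift below ~30%
identity, yet protein structure stays recognisable long after the
sequences have saturated. `trmsd` classifies a set of homologous proteins
**by structure**: given a multiple sequence alignment and one coordinate
set per sequence, it produces a clustering tree of the structures in
which every node carries the number of alignment positions supporting it
— a bootstrap-like support, but counted over ungapped columns instead of
resamples. It is aimed at structural biologists and bioinformaticians who
want to resolve conformational or functional subfamilies (closely related
GTPase subfamilies, cysteine-rich domain variants, and the like) at a
finer grain than whole-fold classifications provide.

## The statistic at the core

Let the *ungapped columns* be the alignment columns with a residue in
every sequence and a resolved representative atom (CA by default) in
every structure, and let `d_A(c, c')` be the intramolecular distance
between structure A's atoms at ungapped columns `c` and `c'`. For each of
the `K` ungapped columns a distance matrix over the structures is built
from a restricted distance-RMSD (dRMSD):

    M_c(A, B) = sqrt( (1 / (K - 1)) * sum_{c' != c} ( d_A(c,c') - d_B(c,c') )^2 )

Because only intramolecular distances enter, the result is invariant to
rigid motion of every input — no superposition is ever computed. Each
matrix becomes an unrooted tree via neighbor joining (re-implemented;
Saitou–Nei Q criterion with standard limb lengths), and the `K` trees are
combined by strict majority-rule consensus: a bipartition is kept exactly
when more than `K/2` column trees contain it, and its support is that
count. Every column is then scored for *discriminativeness* — the
fraction of consensus bipartitions its own tree recovers — and mapped on
a blue (uninformative) to red (highly discriminant) colour ramp.

## A worked example

The bundled generator fabricates a protein family with planted
conformational clusters — here three subfamilies of four structures, 40
residues each, differing by 30° hinge motions of the C-terminal domain,
with 0.1 Å coordinate noise and a random rigid motion per structure:

```r
library(trmsd)
fam <- make_family(n_clusters = 3, per_cluster = 4, n_residues = 40,
                   noise_sigma = 0.1, angle_step = 30, seed = 1)
fit <- trmsd(fam$msa, structures = fam$structures)
fit
#> Structure-based clustering of 12 sequences
#>   ungapped columns (K): 40 of 40 alignment columns
#>   consensus splits: 3 (max possible 9)
#>   split support: 25-37 columns (of 40)
#>   mean column discriminativeness: 0.808
```

All 40 columns are usable (`K = 40`); the consensus contains 3
bipartitions — exactly the three planted subfamilies — each supported by
25–37 of the 40 per-column trees:

```r
newick_string(fit$consensus, "count")
#> (c1_s1,c1_s2,c1_s3,c1_s4,((c2_s1,c2_s2,c2_s3,c2_s4)25,(c3_s1,c3_s2,c3_s3,c3_s4)35)37);
```

`summary(fit)` ranks the columns: the most discriminant positions (score
1.0, i.e. their individual trees reproduce the full consensus) sit inside
the hinged domain, while static positions score lower:

```r
summary(fit)
#> trmsd run: 12 sequences, 40/40 ungapped columns
#> Consensus: 3 splits; supports: 37, 25, 35
#> Column discriminativeness:
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.0000  0.6667  0.8333  0.8083  1.0000  1.0000
```

With file inputs the same run is
`trmsd("msa.fasta", templates = "templates.tsv", out_dir = "out")`, which
writes `consensus.nwk`, the per-column trees and matrices, a
`column_scores.tsv`, a colour-coded HTML alignment and a `run_log.json`.
A command-line wrapper with `run`, `simulate` and `score` subcommands is
installed under `inst/scripts/trmsd`.

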