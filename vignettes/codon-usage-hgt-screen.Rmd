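---
title: "Compositional screening for horizontally transferred genes"
author: "codonscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional screening for horizontally transferred genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonscreen)
```

## The problem

Bacterial genomes are compositionally coherent: mutational pressure and
translational selection give each genome a characteristic G+C content and a
characteristic pattern of synonymous codon choice. A gene acquired recently
by horizontal gene transfer (HGT) still carries its donor's signature, so a
gene whose codon usage and third-position G+C deviate strongly from the rest
of its own genome is a transfer candidate. Marine halophiles such as
*Halomonas* live in mobile-gene-rich environments, and their heavy-metal
resistance determinants (mercury *mer* operons, P-type ATPases, RND efflux
systems) are classic cargo of such transfers, which makes a lightweight,
reproducible compositional screen genuinely useful: it needs only the genome
and its CDS annotations, no database searches.

`codonscreen` implements that screen end to end, together with the genome
report statistics and the distance-based phylogenetic placement that
accompany a genome announcement, and a synthetic-genome generator that makes
every stage testable without downloading anything.

## The screen

### Relative synonymous codon usage

For codon $c$ encoding amino acid $a$ with synonymous family
$\mathrm{syn}(a)$ of size $k_a$,

$$\mathrm{RSCU}_c \;=\; \frac{n_c}{\frac{1}{k_a}\sum_{c' \in \mathrm{syn}(a)} n_{c'}},$$

the observed count over the count expected if all synonymous codons were
used equally; 1 means unbiased, values above 1 mean preference. Two
representational decisions matter downstream:

* **Undefined is not zero.** When an amino acid does not occur in a gene,
  every codon of its family has RSCU `NA`, never 0. A zero means the amino
  acid is present and the codon avoided; the fold-change logic must be able
  to tell these apart.
* **Stop codons never receive an RSCU** and Met (ATG) and Trp (TGG) have no
  synonymous alternative, so the screen operates on the 59-codon degenerate
  universe of the bacterial genetic code (translation table 11, the
  default; the universe is recomputed if another table is chosen).

### The gene-level rule

Each gene is compared against the **pooled background**: the element-wise
sum of the codon-count tables of *all* protein-coding genes, profiled once.
Pooling (rather than averaging per-gene profiles) weights genes by their
codon count, which is what a genome-wide usage table should do. The
screened gene itself stays in the pool: for realistic gene sets its own
contribution is negligible, and keeping it makes the background a fixed,
auditable quantity that does not change per gene.

For every degenerate codon the gene actually uses, the screen computes the
symmetric fold change

$$f_c = \max\!\left(\frac{g_c}{b_c},\, \frac{b_c}{g_c}\right),$$

where $g_c$ and $b_c$ are gene and background RSCU. Symmetry is deliberate:
a transferred gene may over- or under-use a codon relative to its host, and
"changed more than two-fold" should not depend on direction. A codon used by
the gene but absent from the background maps to $+\infty$ (changed); a codon
the gene does not use, or whose background RSCU is undefined, is excluded
from the denominator.

The gene is flagged when

$$\frac{\#\{c : f_c > F\}}{n_\mathrm{used}} > q,$$

with defaults $F = 2$ and $q = 0.25$, both strict inequalities. The
denominator $n_\mathrm{used}$ is the number of degenerate codons the gene
uses, not the fixed 59: short genes use far fewer than 59 codons, and a
fixed denominator would make the rule silently more conservative for them.
The fraction over the fixed universe is reported alongside
(`fraction_changed_universe`) so both conventions are always visible.

### GC deviations

`gc_metrics()` reports overall G+C, positional GC1/GC2/GC3, and two
third-position variants: `gc3_all` over all counted codons and `gc3_syn`
restricted to the degenerate universe (the GC3s of codon-usage programs).
The screen's deltas use `gc3_syn`, because synonymous third positions are
where mutational signature shows with the least selective interference;
`gc3_all` is computed and exported for comparison. The GC flag fires when
either the GC or GC3s deviation from the background exceeds
`gc_delta_threshold` (default 5 percentage points — conservative relative to
the ~9-point GC and ~20-point GC3 deviations of clear-cut transferred
operons; the raw signed deltas are always reported next to the flag, so the
threshold only affects the boolean, not the evidence).

### Taxonomy and the combined verdict

The second, independent line of evidence is the taxon of each gene's closest
database relative, consumed as a pre-computed table (the package never runs
a homology search). `classify_hit()` takes the genus as the first token of
the organism name (so "*Halomonas* sp." resolves by genus), maps it to a
family through a packaged genus-to-family table, and calls the hit *foreign*
when the family differs from `self_family` (default Halomonadaceae). A
genus missing from the map yields `NA`, is excluded from tallies, and is
messaged — an unknown genus must never silently count as self.

Composition and taxonomy are *not* collapsed into one boolean. Recent
transfers show both signals; ameliorated transfers keep the foreign best
hit but lose the compositional signal; native genes under unusual selection
can show composition only. `screen_genome()` therefore reports an
`evidence_class` in {`both`, `composition_only`, `taxonomy_only`, `none`}
and leaves the final judgement to the analyst.

## Genome report statistics

* **N50** follows the descending-cumulative definition: sort contig lengths
  descending, accumulate, report the first length at which the running sum
  reaches half the assembly.
* **Coding density** is the union footprint of CDS features per contig
  (computed with `IRanges::reduce`), so overlapping genes are counted once
  and density cannot exceed 100%.
* **Percentages** are recomputed from counts, never trusted from input, and
  rounded to two decimals *half-up* (with an epsilon guard against binary
  representation artefacts), matching how report tables are printed.
* **COG tables** use the dual-denominator convention of published genome
  reports: category percentages divide by the total number of
  category *assignments* (a gene carrying two categories contributes
  twice), while the "Not in COGs" percentage divides by the total gene
  count. Both denominators are carried in the result, and a
  uniform-denominator mode is available for callers who prefer
  comparability over table reproduction.

## Phylogenetic placement

The placement stack takes a pre-aligned FASTA (alignment itself is out of
scope) and applies the classic distance pipeline:

* **K2P distances** with pairwise deletion (sites where either sequence has
  a gap or ambiguity code are dropped per pair; complete deletion is
  available via a flag). Saturation — a non-positive argument to either
  logarithm — is an error naming the offending pair, not a silent `NaN`.
* **Neighbor-joining** (Saitou–Nei Q-criterion) is implemented in-package
  so its numerical behaviour is fully specified: ties on the minimal Q are
  broken by the lowest (row, column) index pair in the current taxa
  ordering, and negative branch-length estimates are clamped to zero with
  the total deficit recorded on the tree. Tests verify both topology and
  path lengths against additive matrices and against an independent
  reference implementation (`ape::nj`).
* **Bootstrap** resamples alignment columns with replacement under one
  seed; the support of each internal edge is the percentage of successful
  replicates containing that bipartition. Saturated replicates are skipped
  and counted. All supports are kept in the tree object;
  `display_supports()` blanks values below 60 for figure-style display only.

## The synthetic-genome generator

`make_profile(gc3_bias)` builds a codon profile by placing probability mass
`gc3_bias` on the G/C-ending codons of each synonymous family;
`simulate_genome()` then emits genes as ATG + iid amino acids (uniform over
the 20 by default — the screen is RSCU-based and deliberately insensitive
to amino-acid composition) encoded through the profile + a stop codon, with
lengths uniform in a range. The default study conditions are 200 background
genes at GC3s 0.85 versus 10 alien genes at GC3s 0.25, lengths 300–600
codons — a GC3-rich halophile genome with a small, strongly divergent
planted operon. Determinism is structural: every gene draws from its own
seed substream, so the same seed reproduces byte-identical FASTA and adding
genes never rewrites earlier ones.

What the generator does **not** emulate — and what passing recovery tests
therefore do not show about real data: amelioration (donor signatures
decaying over residence time), within-genome heterogeneity (highly
expressed genes, strand bias, local GC isochores), operon structure and
length-dependent composition, or realistic amino-acid usage. Real screens
see a continuum of divergence, not two clean populations; the planted-gene
recovery rates here are an upper bound on sensitivity and a sanity check on
the machinery, not a benchmark of the method's field performance.

## Numerical and degenerate-input choices

* CDS lengths not divisible by three are kept with a warning and the
  trailing partial codon is dropped at codon-counting time (draft-genome
  feature tables contain such records; rejecting them would be worse).
* Codons containing ambiguity characters are excluded from counts and
  tallied (`n_excluded`), never guessed.
* Annotation rows written high-to-low (as minus-strand genes often are in
  report tables) are normalized to `start <= end` silently; strand alone
  carries orientation. Coordinates are 1-based inclusive end to end.
* A gene with zero degenerate codons cannot be screened and is an error; a
  background with an absent amino acid makes those codons not-applicable
  rather than changed.
* `fold_change` is total by construction: every combination of
  defined/undefined/zero inputs maps to a number, `Inf`, or `NA`.

## Problem sizes used by the test suite

Property-style tests run 1,000 random genes for the RSCU closure and
scale-invariance invariants, 1,000 random length lists for the N50 oracle
check, additive matrices up to six taxa for neighbor-joining recovery, and
synthetic genomes of 40–210 genes for screen monotonicity and recovery; the
full suite completes in well under a minute. These sizes were chosen to
exercise the asymptotics the invariants describe while keeping the suite
fast enough to run on every change.

## Limitations

The screen is compositional: it cannot date transfers, identify donors, or
detect ameliorated transfers, and unusual native genes (e.g. highly
expressed ribosomal proteins) can be compositionally atypical without being
foreign. The taxonomy verdict inherits the biases of whatever database
produced the best hits, and the packaged genus-to-family map covers common
genera only — extend it with `default_taxonomy(extra = ...)` for other
clades. Neighbor-joining is a point estimate; bootstrap supports quantify
resampling stability, not model adequacy.
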