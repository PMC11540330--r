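---
title: "Measuring codon usage bias and its evolution with cubevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring codon usage bias and its evolution with cubevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubevol)
```

## The problem

Synonymous codons are not used at random. Two forces dominate their usage in
budding yeasts: mutational bias, which pushes third codon positions toward G/C
or A/T wholesale, and translational selection, which favours codons read by
abundant tRNAs in highly expressed genes. Budding yeasts are a particularly
rich system for studying this because several orders have gone further and
*reassigned* a codon: nuclear CTG is read as serine (the `ctg_ser` code) or
alanine (`ctg_ala`) rather than leucine, and at least one lineage appears to
have lost the tRNAs needed to decode the four CGN arginine codons altogether.
`cubevol` implements the statistics needed to quantify these forces
genome-by-genome and to trace codon replacement at conserved sites.

## Codon usage metrics

**RSCU.** For codon $c$ of an amino acid with $k$ synonymous codons,
$\mathrm{RSCU}_c = k\, n_c / \sum_{c'} n_{c'}$: the observed count over the
count expected under uniform synonymous usage. Values sum to $k$ within each
family and are scale-invariant. A family absent from a gene gives *undefined*
RSCU for its codons, never zero — and genome-wide averages (unweighted mean
over genes, the default) exclude those genes per codon. A pooled-counts mode
(`genome_average_rscu(..., method = "pooled")`) weights genes by length and is
provided for sensitivity analysis; the two differ on length-heterogeneous
genomes.

```{r rscu}
code <- get_code("standard")
cnt <- new_codon_counts(c(GTT = 60L, GTC = 20L, GTA = 15L, GTG = 5L), code)
rscu(cnt)$values[c("GTT", "GTC", "GTA", "GTG")]
```

**GC3s.** We compute the synonymous third-position G+C fraction over codons
whose third position can change silently: a codon qualifies when another codon
with the same first two bases encodes the same amino acid. Under the standard
code this is the classic 59-codon set (Met, Trp, stops excluded); under the
reassigned codes CTG is additionally excluded, because its third-position
neighbours encode leucine while CTG itself does not. The family-level
alternative ("all codons of degenerate amino acids") is insensitive to the
CTG reassignment and was rejected for that reason.

**Effective number of codons.** Nc is often cited without a formula, so we
adopt Wright's estimator with class-averaged homozygosity
$F_a = (n_a \sum_i p_i^2 - 1)/(n_a - 1)$, generalized to arbitrary degeneracy
classes so that the 7-fold serine family of the `ctg_ser` code is handled
natively. Classes with no estimable $\bar F$ are imputed as the mean of
adjacent estimable classes (the convention long used for the lone 3-fold
class); families with fewer than 2 observations or non-positive $F$ are
skipped, and the result is capped at the number of sense codons. The
composition-only null is Wright's curve
$N_c^{exp}(s) = 2 + s + 29/(s^2 + (1-s)^2)$.

## tRNA pools and the S-value

tRNAscan-SE output is filtered the way genomic tRNA inventories are built:
pseudogenes out (note field containing "pseudo"; no additional score rule,
since the predictor's own call is the criterion), records without a standard
isotype out, and records whose anticodon implies — by reverse complement under
the *active* genetic code — a different amino acid than the predicted isotype
out. Making the code active is what handles the reassigned clades: a Ser-CAG
tRNA is consistent under `ctg_ser` and kept, while the identical record under
the standard code is a mismatch. Records with an isotype but no anticodon
cannot enter the per-anticodon copy table and are removed (audited
separately).

Codon adaptiveness follows the classical tAI construction:
$W_i = \sum_j (1 - s_j)\,\mathrm{tGCN}_j$ over anticodons recognizing codon
$i$, with eukaryotic wobble penalties $s_{G:U} = 0.41$, $s_{I:C} = 0.28$,
$s_{I:A} = 0.9999$, $s_{U:G} = 0.68$ and Watson–Crick pairs at 0 (the
prokaryotic lysidine rule is off by default). These constants are
configuration, not code, and the box-mode $W$ vector is verified in the test
suite against an independent implementation of the reference box-loop
construction. Codons no anticodon can read receive the geometric mean of the
nonzero relative adaptiveness values and are recorded: a genome missing all
CGN decoders is a *state to represent*, not an error. An
`isotype_restricted` mode suppresses cross-family wobble contributions in
split codon boxes (e.g. an Ile TAT anticodon mechanically reading Met's ATG);
it is also the mode in which a reassigned-clade Ser-CAG anticodon feeds CTG.

Gene tAI is the geometric mean of $w$ over the gene's sense codons. The
genome-level S-value correlates tAI with the GC3s-adjusted Nc deviation
$(N_c^{exp}(\mathrm{GC3s}) - N_c)/N_c^{exp}(\mathrm{GC3s})$ across genes
(Pearson by default, Spearman behind a flag). S near 1 means the genes whose
codons match the tRNA pool are exactly the genes most skewed below the
mutational null — translational selection. The S-value is reported as
undefined, with the reason, when fewer than 3 usable genes exist or either
variable is constant.

## Conserved-arginine codon evolution

Protein alignments are inputs (produced by any MSA tool); the package
validates them, back-translates them to codon alignments, and never aligns.
Conservation fractions are computed over non-gap entries by default — a gap
neither supports nor counts against a site — with an all-rows denominator
available for sensitivity. Sites are detected at a configurable residue
threshold (0.8, with 0.6 as the customary secondary threshold; lowering the
threshold can only add sites). Within each group, the consensus codon must
reach the group threshold; at thresholds above 0.5 ties are impossible, and
at exactly 0.5 a tie yields no consensus.

Ancestral codons use Fitch parsimony on the rooted 3-group topology
((ingroup A, ingroup B), outgroup): intersection if nonempty, else union, at
the ingroup node; at the root, an empty intersection with the outgroup is
resolved *toward the outgroup state* and flagged, so downstream summaries can
be recomputed with and without resolved sites. The group labels and topology
are configuration. Branch-level transitions (ancestral to per-ingroup
consensus) feed a transition matrix whose diagonal is retention.

## Phylogenetic comparative statistics

Independent contrasts are delegated to `ape::pic` after polytomy resolution
(zero-length branches, recorded) and missing-tip detection. PGLS with
Pagel's $\lambda$ is implemented directly: the Brownian covariance from
`ape::vcv` has its off-diagonals scaled by $\lambda$, and $\lambda$ is chosen
by restricted maximum likelihood with bounded scalar optimization over
$[10^{-6}, 1]$ at tolerance $10^{-6}$. If the optimization fails — e.g. a
degenerate response — $\lambda$ is set to 1, the most conservative choice,
and flagged. Slope inference uses the t distribution with $n - 2$ degrees of
freedom; the pairwise screen corrects with Benjamini–Hochberg (chosen here;
other corrections would be defensible).

## What the simulators emulate

The generators exist so every stage can be exercised with known truth:

* `simulate_cds_set` draws each codon with probability
  $\propto m(c)\exp(\sigma \phi_g w_c)$: $m$ weights every G/C-ending codon
  $\beta$ and every A/T-ending codon $1-\beta$ (normalized within the
  family, so $\beta = 0.5$ is exactly neutral), $\phi_g$ is lognormal(0, 1)
  expression, and $w$ comes from the supplied tRNA pool. This is the minimal
  model with the two axes — compositional bias versus translational
  selection — that the S-value is designed to separate. Defaults are 2,000
  genes of lognormal length around 400 codons (the typical scale of a yeast
  CDS), uniform amino-acid composition, and a deterministic skewed pool (one
  major anticodon per family at 8 copies over a single-copy background).
* `simulate_trna_pool` writes genuine tRNAscan-SE-format files, optionally
  salted with pseudogenes and isotype mismatches, and can delete all four
  CGN-decoding anticodons to mimic the CGN-loss state.
* `simulate_ortholog_families` plants arginine-conserved columns with exact
  per-group codon fractions (placed deterministically, so a 0.75-conserved
  site sits precisely on the 0.8/0.6 threshold boundary) and emits a truth
  manifest whose intended ancestral states come from a brute-force parsimony
  enumeration, independent of the analysis-side implementation.
* `simulate_tree_and_traits` produces pure-birth trees with Brownian traits
  and a planted linear relation for regression recovery.

A single root seed fans out to fixed per-component substreams, so adding a
generator never changes another's output. What the simulators do *not*
emulate: real gene-length/composition correlations, alignment error, indels
at conserved sites, assembly incompleteness, and sequence evolution along
trees beyond the planted-site scheme. Passing tests therefore demonstrate
correctness of the statistics under the stated model, not the field behaviour
of the upstream predictors and aligners.

## Numerical choices and problem sizes

Nc is undefined (never 0) when no class is estimable; GC statistics are NA
on zero eligible positions; genes shorter than 30 codons are flagged since
Nc is unstable there. The test suite verifies the neutral-sampler symmetry
at roughly $4 \times 10^5$ codons, where three multinomial standard
deviations of a six-fold family stay below the 0.05 assertion band; S-value
recovery uses 2,000 genes for the neutral bound and 400 genes per point for
the monotonicity sweep; PGLS recovery uses 200 tips. These sizes were chosen
so each statistical assertion has adequate power.

## Worked example

```{r example}
code <- get_code("standard")
tgcn <- skewed_anticodon_pool(code)
pool <- new_trna_pool(tgcn, code)
adapt <- build_adaptiveness(pool, code = code)
g <- simulate_cds_set(n_genes = 200, mean_length = 200,
                      selection_strength = 2, tgcn = tgcn, seed = 42)
counts <- lapply(names(g$sequences), function(id)
  count_codons(g$sequences[[id]], code, id))
stats <- genome_selection_stats(counts, adapt, code)
s_value(stats)
```

## Known limitations

The S-value inherits every bias of the genomic tRNA pool as an abundance
proxy; wobble penalties are fixed constants, not fitted. The 3-group
parsimony is deliberately minimal — likelihood ancestral reconstruction and
more taxa are out of scope. PGLS assumes a single $\lambda$ for the
residuals, and the polytomy resolution is arbitrary (though recorded).
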