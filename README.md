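# cubevol

Genetic-code–aware analysis of codon usage bias and its evolution in yeast
genomes, including the budding-yeast clades whose nuclear CTG codon is
reassigned to serine or alanine.

Synonymous codon usage is shaped by two separable forces: **mutational bias**
(third codon positions drifting toward G/C or A/T) and **translational
selection** (preference for codons read by abundant tRNAs, strongest in
highly expressed genes). `cubevol` is for researchers who want to quantify
both forces per genome and to trace codon replacement at conserved sites —
for example the repeated CGN → AGN arginine switches seen in lineages that
have lost their CGN-decoding tRNAs.

## What it computes

* **RSCU** — relative synonymous codon usage,
  RSCU_c = k·n_c / Σ n_c′, per gene and as genome-wide averages, under the
  standard, CTG-Ser and CTG-Ala nuclear codes (`get_code`, `rscu`,
  `genome_average_rscu`).
* **GC, GC3, GC3s** and the **effective number of codons** Nc — Wright's
  estimator with class-averaged homozygosity
  F_a = (n_a·Σp_i² − 1)/(n_a − 1), generalized to any degeneracy structure
  (7-fold serine under CTG-Ser), with the null curve
  Nc_exp(s) = 2 + s + 29/(s² + (1−s)²) (`gene_codon_stats`,
  `effective_number_of_codons`, `expected_nc`).
* **tRNA inventories** — a tRNAscan-SE 2.x parser and the standard
  filtering (pseudogenes, missing isotypes, anticodon/isotype mismatches
  under the *active* code, so Ser-CAG tRNAs survive in reassigned clades)
  into per-anticodon gene-copy numbers, tRNA-ome size and
  anticodon-repertoire diagnostics (`parse_trnascan`, `filter_trnas`,
  `anticodon_diagnostics`).
* **tAI and the S-value** — codon adaptiveness
  W_i = Σ_j (1 − s_j)·tGCN_j under eukaryotic wobble penalties, gene tAI as
  the geometric mean of w, and the genome S-value: the correlation between
  tAI and (Nc_exp(GC3s) − Nc)/Nc_exp(GC3s) across genes, ≈1 under strong
  translational selection and ≈0 without it (`build_adaptiveness`,
  `gene_tai`, `s_value`).
* **Conserved-residue codon evolution** — protein-guided back-translation,
  conserved-site detection at configurable thresholds (0.8/0.6), per-group
  codon consensus, Fitch-parsimony ancestral codons on a rooted
  ((A,B),outgroup) topology, and ancestral→descendant transition tables
  (`back_translate_alignment`, `conserved_site_report`,
  `transition_table`).
* **Phylogenetic comparative fits** — independent contrasts and PGLS with
  maximum-likelihood Pagel's λ in [1e-6, 1] (λ := 1 on optimizer failure),
  with a BH-corrected pairwise trait screen (`pic_regression`,
  `pgls_lambda`, `trait_pair_screen`).
* **Seeded simulators** for all of the above: CDS sets drawn under a
  mutation × selection codon model, tRNAscan-format pools, ortholog
  families with planted conserved sites, and Brownian traits on pure-birth
  trees (`simulate_cds_set`, `simulate_trna_pool`,
  `simulate_ortholog_families`, `simulate_tree_and_traits`).

## Worked example

```r
library(cubevol)
code <- get_code("standard")

# RSCU: 60 GTT among 100 valine codons
cnt <- new_codon_counts(c(GTT = 60L, GTC = 20L, GTA = 15L, GTG = 5L), code)
rscu(cnt)$values[c("GTT", "GTC", "GTA", "GTG")]
#> GTT GTC GTA GTG
#> 2.4 0.8 0.6 0.2

# S-value on a simulated genome under strong translational selection
tgcn  <- skewed_anticodon_pool(code)
adapt <- build_adaptiveness(new_trna_pool(tgcn, code), code = code)
g <- simulate_cds_set(n_genes = 200, mean_length = 200,
                      selection_strength = 2, tgcn = tgcn, seed = 42)
counts <- lapply(names(g$sequences), function(id)
  count_codons(g$sequences[[id]], code, id))
stats <- genome_selection_stats(counts, adapt, code)
s_value(stats)
#> S-value: 0.932 (pearson, 200 genes, 0 dropped)
```

GTT occurs 60 times where uniform usage of the four valine codons would
predict 25, so its RSCU is 4 × 60/100 = 2.4; the other valine codons share
the remainder (their RSCUs sum to 4 with it). The simulated genome couples
codon choice to expression and tRNA supply, and the S-value near 1 reports
exactly that coupling; rerunning with `selection_strength = 0` drops it to
sampling noise around 0.

An end-to-end per-genome profile (RSCU matrix, GC metrics, tRNA-ome,
S-value) is available as `run_genome_profile()`, and the conserved-arginine
pipeline as `run_conserved_residue()`; both have a thin command-line wrapper
in `inst/scripts/cubevol-profile.R`. The methods vignette
(`vignettes/codon-usage-methods.Rmd`) documents the models, defaults and
numerical conventions.

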