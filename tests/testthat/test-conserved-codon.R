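test_that("back-translation maps residues to codons and gaps to gap codons", {
  prot <- c(s1 = "M-S", s2 = "MTS")
  cds <- c(s1 = "ATGTCT", s2 = "ATGACTTCA")
  aln <- back_translate_alignment(prot, cds, std)
  expect_equal(aln$rows[["s1"]], "ATG---TCT")
  expect_equal(aln$rows[["s2"]], "ATGACTTCA")

  # terminal stop tolerated
  aln2 <- back_translate_alignment(c(s1 = "MS"), c(s1 = "ATGTCTTAA"), std)
  expect_equal(aln2$rows[["s1"]], "ATGTCT")

  # mismatching CDS rejected with the label named
  expect_error(back_translate_alignment(c(s1 = "MS"), c(s1 = "ATGGCT"), std),
               "s1")
})

test_that("back-translation round-trips on random gapped families", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 4L; len <- 20L
    cds <- setNames(replicate(n, random_cds(len)), paste0("t", 1:n))
    prot <- vapply(cds, function(s) translate_cds(s, std), character(1))
    # insert a shared gap column at a random position
    gap_at <- sample(len, 1)
    gapped <- vapply(prot, function(p) {
      paste0(substr(p, 1, gap_at - 1), "-", substr(p, gap_at, len))
    }, character(1))
    # one row keeps its residue there; give it one extra residue
    aln <- back_translate_alignment(gapped, cds, std)
    ungapped <- gsub("---", "", aln$rows, fixed = TRUE)
    for (lab in names(cds)) {
      expect_equal(translate_cds(ungapped[[lab]], std), prot[[lab]])
    }
  }
})

test_that("conserved-site detection respects thresholds and gap policy", {
  prot <- c(t1 = "RA", t2 = "RA", t3 = "RA", t4 = "RA", t5 = "RA",
            t6 = "RA", t7 = "RA", t8 = "RG", t9 = "RG", t10 = "-G")
  # column 1: 9 R out of 9 non-gap; column 2: no R
  expect_equal(conserved_residue_sites(prot, "R", 0.8), 1L)
  expect_equal(conserved_residue_sites(prot, "R", 1.0), 1L)

  prot2 <- c(t1 = "R", t2 = "R", t3 = "R", t4 = "R", t5 = "R",
             t6 = "R", t7 = "R", t8 = "K", t9 = "K", t10 = "K")
  expect_length(conserved_residue_sites(prot2, "R", 0.8), 0)
  expect_equal(conserved_residue_sites(prot2, "R", 0.6), 1L)

  allgap <- c(t1 = "-R", t2 = "-R", t3 = "-R")
  expect_equal(conserved_residue_sites(allgap, "R", 0.8), 2L)

  # denominator mode: 9 R / 10 rows with 1 gap
  prot3 <- c(t1 = "R", t2 = "R", t3 = "R", t4 = "R", t5 = "R",
             t6 = "R", t7 = "R", t8 = "R", t9 = "R", t10 = "-")
  expect_equal(conserved_residue_sites(prot3, "R", 1.0), 1L)
  expect_length(conserved_residue_sites(prot3, "R", 1.0,
                                        denominator = "all"), 0)
})

test_that("lowering the threshold never removes sites", {
  set.seed(19)
  for (rep in 1:5) {
    prot <- setNames(replicate(8, paste(sample(c("R", "K", "A"), 30,
                                               replace = TRUE,
                                               prob = c(0.6, 0.2, 0.2)),
                                        collapse = "")),
                     paste0("t", 1:8))
    s80 <- conserved_residue_sites(prot, "R", 0.8)
    s60 <- conserved_residue_sites(prot, "R", 0.6)
    expect_true(all(s80 %in% s60))
  }
})

test_that("group consensus honours thresholds and exact ties", {
  mk_aln <- function(codons) {
    structure(list(rows = setNames(codons, paste0("t", seq_along(codons))),
                   n_columns = 1L, code_id = "standard"),
              class = "codon_alignment")
  }
  a5 <- mk_aln(rep("AGA", 5))
  expect_equal(group_codon_consensus(a5, 1, names(a5$rows), 0.8), "AGA")
  a41 <- mk_aln(c(rep("AGA", 4), "CGT"))
  expect_equal(group_codon_consensus(a41, 1, names(a41$rows), 0.8), "AGA")
  a32 <- mk_aln(c(rep("AGA", 3), rep("CGT", 2)))
  expect_true(is.na(group_codon_consensus(a32, 1, names(a32$rows), 0.8)))
  # exact tie at 0.5
  a22 <- mk_aln(c("AGA", "AGA", "CGT", "CGT"))
  expect_true(is.na(group_codon_consensus(a22, 1, names(a22$rows), 0.5)))
})

test_that("three-taxon parsimony matches exhaustive enumeration", {
  enumerate <- function(a, b, o) {
    states <- unique(c(a, b, o))
    best <- Inf; roots <- character(0)
    for (root in states) for (node in states) {
      cost <- (root != node) + (node != a) + (node != b) + (root != o)
      if (cost < best) { best <- cost; roots <- root }
      else if (cost == best) roots <- union(roots, root)
    }
    list(roots = roots, cost = best)
  }
  codes <- c("AGA", "AGG", "CGT", "CGC")
  for (a in codes) for (b in codes) for (o in codes) {
    fit <- ancestral_codon_fitch(a, b, o)
    ref <- enumerate(a, b, o)
    expect_true(fit$ancestral %in% ref$roots,
                info = paste(a, b, o))
    # inferred changes over all four branches equal the parsimony cost
    expect_equal(nrow(fit$transitions), ref$cost, info = paste(a, b, o))
    # outgroup-preferred resolution
    if (o %in% ref$roots) expect_equal(fit$ancestral, o)
  }
  expect_equal(ancestral_codon_fitch("AGA", "AGA", "AGA")$transitions,
               data.frame(branch = character(0), from = character(0),
                          to = character(0), stringsAsFactors = FALSE))
  f <- ancestral_codon_fitch("AGA", "AGA", "CGT")
  expect_equal(f$ancestral, "CGT")
  expect_true(f$outgroup_resolved)
  expect_equal(f$transitions$branch, "ingroup_stem")
  f2 <- ancestral_codon_fitch("AGA", "CGT", "CGT")
  expect_equal(f2$ancestral, "CGT")
  expect_false(f2$outgroup_resolved)
  expect_equal(f2$transitions$to, "AGA")
})

test_that("mutation distances reproduce the CGN-to-AGN geometry", {
  expect_equal(mutation_distance("CGA", "AGA"), 1L)
  expect_equal(mutation_distance("CGT", "AGA"), 2L)
  expect_equal(mutation_distance("AGA", "AGA"), 0L)
  expect_error(mutation_distance("CG-", "AGA"), "invalid")
  dists <- outer(CGN <- c("CGT", "CGC", "CGA", "CGG"),
                 AGN <- c("AGA", "AGG"),
                 Vectorize(mutation_distance))
  expect_equal(sum(dists == 2), 6L)
  expect_equal(sum(dists == 1), 2L)
})

test_that("planted families are recovered exactly at zero codon noise", {
  sim <- simulate_ortholog_families(n_families = 8, noise_rate = 0, seed = 23)
  res <- run_conserved_residue(sim$families, sim$groups, sim$topology)
  expect_equal(res$n_sites, nrow(sim$truth))
  expect_equal(sort(res$report$column), sort(sim$truth$column))
  expect_equal(res$report$ancestral[order(res$report$ortholog_id)],
               sim$truth$ancestral[order(sim$truth$family)])
  # transition matrix equals the planted branch-level truth
  g <- sim$topology
  anc <- rep(sim$truth$ancestral, 2)
  des <- c(sim$truth[[g[1]]], sim$truth[[g[2]]])
  expected <- table(anc, des)
  got <- res$transitions$matrix
  for (i in rownames(expected)) for (j in colnames(expected))
    expect_equal(got[i, j], unname(expected[i, j]))
})

test_that("a 0.75-conserved codon passes at 0.6 but fails at 0.8", {
  planted <- data.frame(family = 1L, column = 5L,
                        A = "AGA", B = "AGA", O = "CGT",
                        frac_A = 0.75, frac_B = 1, frac_O = 1,
                        stringsAsFactors = FALSE)
  sim <- simulate_ortholog_families(n_families = 1, planted = planted,
                                    noise_rate = 0, seed = 29)
  strict <- run_conserved_residue(sim$families, sim$groups, sim$topology,
                                  group_threshold = 0.8)
  loose <- run_conserved_residue(sim$families, sim$groups, sim$topology,
                                 group_threshold = 0.6)
  expect_true(is.na(strict$report$ancestral[1]))
  expect_equal(loose$report$ancestral[1], "CGT")
})

test_that("planted transition counts are read back exactly", {
  # 10 planted CGT->AGA transitions (on branch A) and 2 CGT retentions
  rows <- lapply(1:12, function(f) {
    data.frame(family = f, column = 7L,
               A = if (f <= 10) "AGA" else "CGT", B = "CGT", O = "CGT",
               stringsAsFactors = FALSE)
  })
  planted <- do.call(rbind, rows)
  sim <- simulate_ortholog_families(n_families = 12, planted = planted,
                                    noise_rate = 0, seed = 37)
  res <- run_conserved_residue(sim$families, sim$groups, sim$topology)
  m <- res$transitions$matrix
  expect_equal(unname(m["CGT", "AGA"]), 10L)
  # branch A retains CGT twice, branch B twelve times
  expect_equal(unname(m["CGT", "CGT"]), 14L)
  expect_equal(res$transitions$n_ambiguous, 0L)
})

test_that("threshold sweep yields a non-decreasing site count", {
  sim <- simulate_ortholog_families(n_families = 5, noise_rate = 0.08,
                                    seed = 41)
  n80 <- run_conserved_residue(sim$families, sim$groups, sim$topology,
                               global_threshold = 0.8)$n_sites
  n60 <- run_conserved_residue(sim$families, sim$groups, sim$topology,
                               global_threshold = 0.6)$n_sites
  expect_gte(n60, n80)
  expect_error(run_conserved_residue(list(), sim$groups, sim$topology),
               "no ortholog")
})
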