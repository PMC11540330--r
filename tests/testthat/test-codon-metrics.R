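test_that("codon counting is exact, drops ambiguity, and is additive", {
  cc <- count_codons("ATGGTTGTTTAA", std)
  expect_equal(cc$counts[["ATG"]], 1L)
  expect_equal(cc$counts[["GTT"]], 2L)
  expect_equal(cc$total_sense, 3L)
  expect_equal(cc$stop_count, 1L)

  amb <- count_codons("ATGNNAGTT", std)
  expect_equal(amb$total_sense, 2L)
  expect_equal(amb$dropped, 1L)

  expect_error(count_codons("ATGC", std), "divisible")

  set.seed(42)
  for (rep in 1:5) {
    s1 <- random_cds(30); s2 <- random_cds(17)
    joint <- count_codons(paste0(s1, s2), std)
    parts <- count_codons(s1, std) + count_codons(s2, std)
    expect_equal(joint$counts, parts$counts)
  }
})

test_that("counting agrees with an independent tally on random sequences", {
  set.seed(7)
  s <- random_cds(200)
  cc <- count_codons(s, std)
  tal <- oracle_codon_tally(s)
  expect_equal(cc$counts[names(tal)], setNames(as.integer(tal), names(tal)))
})

test_that("RSCU reproduces the valine worked example and the formula", {
  cnt <- counts_from_vec(c(GTT = 60L, GTC = 25L, GTA = 10L, GTG = 5L))
  expect_equal(rscu(cnt)$values[["GTT"]], 2.4)
  # two-fold amino acid with counts (3, 1)
  cnt2 <- counts_from_vec(c(AAA = 3L, AAG = 1L))
  expect_equal(unname(rscu(cnt2)$values[c("AAA", "AAG")]), c(1.5, 0.5))
  # uniform usage within every family gives RSCU 1 everywhere defined
  uni <- counts_from_vec(setNames(rep(2L, 59), std$degenerate_codons))
  vals <- rscu(uni)$values
  expect_true(all(abs(vals - 1) < 1e-12))
})

test_that("RSCU sums to k_a per family, is scale invariant, and flags absent", {
  set.seed(11)
  vec <- setNames(rpois(61, 8), std$sense_codons)
  vec[codons_for_aa("His", std)] <- 0L  # histidine absent
  prof <- rscu(counts_from_vec(vec))
  for (aa in names(std$degeneracy)) {
    if (std$degeneracy[[aa]] < 2) next
    fam <- codons_for_aa(aa, std)
    if (aa == "His") {
      expect_true(all(fam %in% prof$undefined_codons))
    } else {
      expect_equal(sum(prof$values[fam]), std$degeneracy[[aa]])
    }
  }
  prof10 <- rscu(counts_from_vec(vec * 10L))
  expect_equal(prof10$values, prof$values)
})

test_that("genome-average RSCU is an unweighted gene mean with NA exclusion", {
  g1 <- rscu(counts_from_vec(c(GTT = 2L, GTC = 1L, GTA = 1L)))  # RSCU GTT 2
  g2 <- rscu(counts_from_vec(c(GTT = 1L, GTC = 1L, GTA = 1L, GTG = 1L)))
  g3 <- rscu(counts_from_vec(c(AAA = 4L)))  # no valine
  avg <- genome_average_rscu(list(g1, g2, g3))
  expect_equal(avg$values[["GTT"]], mean(c(2, 1)))
  expect_equal(unname(avg$n_genes["GTT"]), 2L)
  # idempotence on identical profiles
  same <- genome_average_rscu(list(g1, g1, g1))
  expect_equal(same$values, g1$values)
})

test_that("mean-of-genes and pooled-count averages differ on length-heterogeneous input", {
  short <- counts_from_vec(c(GTT = 1L, GTC = 1L))
  long <- counts_from_vec(c(GTT = 90L, GTC = 10L))
  by_gene <- genome_average_rscu(list(rscu(short), rscu(long)))
  pooled <- genome_average_rscu(list(short, long), method = "pooled")
  expect_false(isTRUE(all.equal(by_gene$values[["GTT"]],
                                pooled$values[["GTT"]])))
})

test_that("GC statistics match a position-by-position oracle", {
  # pure-GCG gene
  st <- gene_codon_stats(count_codons("GCGGCGGCG", std))
  expect_equal(st$gc3, 1)
  expect_equal(st$gc3s, 1)
  # only Met and Trp: gc3s undefined
  st2 <- gene_codon_stats(count_codons("ATGTGG", std))
  expect_true(is.na(st2$gc3s))
  # random sequence against brute force
  set.seed(5)
  s <- random_cds(300)
  st3 <- gene_codon_stats(count_codons(s, std))
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  third <- substr(codons, 3, 3)
  syn <- codons %in% synonymous_third_codons(std)
  expect_equal(st3$gc3s, mean(third[syn] %in% c("G", "C")))
  expect_equal(st3$gc3, mean(third %in% c("G", "C")))
  allbases <- strsplit(paste(codons, collapse = ""), "")[[1]]
  expect_equal(st3$gc, mean(allbases %in% c("G", "C")))
})

test_that("gc3 of an all-G-third gene is 1 even in a stopless frame", {
  st2 <- gene_codon_stats(count_codons("ATGTGG", std))
  expect_equal(st2$gc3, 1)
})

test_that("GC3s responds to the active code on CTG-rich genes", {
  s <- paste(rep("CTG", 50), collapse = "")
  s <- paste0(s, "CTTTTA")  # some leucine diversity
  std_val <- gene_codon_stats(count_codons(s, std), std)$gc3s
  ser_val <- gene_codon_stats(count_codons(s, get_code("ctg_ser")),
                              get_code("ctg_ser"))$gc3s
  expect_false(isTRUE(all.equal(std_val, ser_val)))
})

test_that("Nc hits its bounds and matches the homozygosity oracle", {
  one_per_aa <- sapply(names(std$degeneracy),
                       function(a) codons_for_aa(a, std)[1])
  low <- counts_from_vec(setNames(rep(50L, 20), one_per_aa))
  expect_equal(effective_number_of_codons(low), 20)

  # near-uniform usage approaches 61
  big <- counts_from_vec(setNames(rep(10000L, 61), std$sense_codons))
  expect_gte(effective_number_of_codons(big), 60.5)

  # constructed toy table vs independent oracle
  vec <- setNames(integer(61), std$sense_codons)
  vec[codons_for_aa("Lys", std)] <- c(7L, 3L)
  vec[codons_for_aa("Val", std)] <- c(5L, 5L, 2L, 0L)
  vec[codons_for_aa("Ser", std)] <- c(9L, 1L, 1L, 1L, 0L, 0L)
  cnt <- counts_from_vec(vec)
  expect_equal(effective_number_of_codons(cnt), oracle_nc(cnt$counts))

  set.seed(9)
  for (rep in 1:5) {
    cc <- count_codons(random_cds(150), std)
    expect_equal(effective_number_of_codons(cc), oracle_nc(cc$counts))
  }
})

test_that("Nc decreases monotonically as within-family usage skews", {
  skew_counts <- function(alpha) {
    # alpha = 0 uniform; alpha -> 1 single codon per family
    vec <- setNames(numeric(61), std$sense_codons)
    for (aa in names(std$degeneracy)) {
      fam <- codons_for_aa(aa, std)
      k <- length(fam)
      p <- (1 - alpha) / k + alpha * (seq_len(k) == 1)
      vec[fam] <- round(p * 3000)
    }
    counts_from_vec(setNames(as.integer(vec), names(vec)))
  }
  ncs <- sapply(c(0, 0.2, 0.4, 0.6, 0.8), function(a)
    effective_number_of_codons(skew_counts(a)))
  expect_true(all(diff(ncs) < 0))
})

test_that("expected-Nc closed form evaluates and is symmetric", {
  expect_equal(expected_nc(0.5), 60.5)
  expect_equal(expected_nc(0), 31)
  expect_equal(expected_nc(1), 32)
  s <- seq(0.05, 0.45, by = 0.05)
  expect_equal(expected_nc(s) - s, expected_nc(1 - s) - (1 - s))
  expect_error(expected_nc(1.2))
})

test_that("arginine census summarizes codon fractions and CGN load", {
  only_aga <- lapply(c(3L, 5L), function(n)
    counts_from_vec(c(AGA = n)))
  cen <- arginine_codon_census(only_aga)
  expect_equal(cen$codon_fractions[["AGA"]], 1)
  expect_equal(cen$zero_cgn_fraction, 1)

  two <- list(counts_from_vec(c(AGA = 2L)),
              counts_from_vec(c(CGT = 2L, CGC = 2L)))
  cen2 <- arginine_codon_census(two)
  expect_equal(cen2$median_cgn, 2)
  expect_equal(cen2$zero_cgn_fraction, 0.5)
  expect_error(arginine_codon_census(list()), "empty")
})

test_that("census fractions converge to the sampling law", {
  set.seed(21)
  probs <- c(CGT = 0.05, CGC = 0.05, CGA = 0.02, CGG = 0.03,
             AGA = 0.7, AGG = 0.15)
  n_per <- 200L
  tx <- lapply(1:60, function(i) {
    tab <- table(sample(names(probs), n_per, replace = TRUE, prob = probs))
    counts_from_vec(setNames(as.integer(tab), names(tab)))
  })
  cen <- arginine_codon_census(tx)
  total <- 60L * n_per
  for (cod in names(probs)) {
    se <- sqrt(probs[[cod]] * (1 - probs[[cod]]) / total)
    expect_lt(abs(cen$codon_fractions[[cod]] - probs[[cod]]), 3 * se + 1e-9)
  }
})

test_that("FASTA round trip feeds the counting path", {
  set.seed(3)
  seqs <- setNames(replicate(4, random_cds(40, stop_tail = TRUE)),
                   paste0("g", 1:4))
  tmp <- tempfile(fileext = ".fa")
  writeLines(paste0(">", names(seqs), "\n", seqs), tmp)
  counts <- read_cds_counts(tmp, std)
  expect_named(counts, names(seqs))
  expect_equal(counts$g1$counts, count_codons(seqs[["g1"]], std)$counts)
})
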