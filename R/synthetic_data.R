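#' Derive a per-component substream seed from a root seed
#'
#' A single root seed fans out to fixed per-component substreams so that
#' adding a generator never perturbs the draws of an existing one.
#'
#' @param seed root seed (integer)
#' @param component generator name
#' @return integer seed below 2^31
#' @export
substream_seed <- function(seed, component = c("trna", "cds", "ortholog",
                                               "tree")) {
  component <- match.arg(component)
  offset <- c(trna = 101L, cds = 211L, ortholog = 307L, tree = 401L)
  as.integer((as.numeric(seed) * 7919 + offset[[component]]) %% 2147483647)
}

#' Default Watson-Crick anticodon set of a code
#' @param code a \code{genetic_code}
#' @return named integer: one anticodon per sense codon, 1 copy each
#' @export
wc_anticodon_pool <- function(code) {
  ac <- revcomp(code$sense_codons)
  stats::setNames(rep(1L, length(ac)), ac)
}

#' Yeast-like skewed anticodon gene-copy pool
#'
#' One Watson-Crick anticodon per sense codon at single copy, with the
#' T-ending (else first) codon of every synonymous family boosted to 8
#' copies.  This mirrors the common situation in yeast genomes where one
#' "major" codon per family is backed by a large tRNA gene family, giving
#' codons distinct adaptiveness so simulated selection has a target.
#'
#' @param code a \code{genetic_code}
#' @param major_copies copy number of the boosted anticodon (default 8)
#' @return named integer vector, anticodon to copies
#' @export
skewed_anticodon_pool <- function(code, major_copies = 8L) {
  tgcn <- wc_anticodon_pool(code)
  for (aa in names(code$degeneracy)) {
    fam <- codons_for_aa(aa, code)
    third <- substr(fam, 3L, 3L)
    major <- if (any(third == "T")) fam[third == "T"][1L] else fam[1L]
    tgcn[revcomp(major)] <- as.integer(major_copies)
  }
  tgcn
}

#' Simulate a tRNA gene pool (optionally as a tRNAscan-SE file)
#'
#' Builds a \code{trna_pool} with the requested per-anticodon copy numbers
#' and, when \code{path} is given, writes the corresponding records in
#' tRNAscan-SE 2.x tabular format.  Pseudogene and isotype-mismatch records
#' can be injected into the file to exercise the filters, and all
#' CGN-decoding anticodons (ACG, GCG, CCG, TCG) can be removed to mimic a
#' genome that has lost the capacity to read CGN arginine codons.
#'
#' @param tgcn named integer, anticodon to copies (default: uniform
#'   Watson-Crick pool over the code's sense codons)
#' @param code a \code{genetic_code}
#' @param n_pseudo pseudogene records to inject into the written file
#' @param n_mismatch isotype-mismatch records to inject
#' @param drop_cgn_decoders remove anticodons reading CGN codons
#' @param path optional output file in tRNAscan-SE layout
#' @param seed RNG seed for injected-record placement
#' @return list with \code{pool} (the filtered truth), \code{path} (or NA),
#'   and \code{n_records_written}
#' @export
simulate_trna_pool <- function(tgcn = NULL, code = get_code("standard"),
                               n_pseudo = 0L, n_mismatch = 0L,
                               drop_cgn_decoders = FALSE, path = NULL,
                               seed = 1L) {
  set.seed(substream_seed(seed, "trna"))
  if (is.null(tgcn)) tgcn <- wc_anticodon_pool(code)
  if (length(tgcn) == 0L) stop("empty anticodon set")
  if (drop_cgn_decoders)
    tgcn <- tgcn[!names(tgcn) %in% c("ACG", "GCG", "CCG", "TCG")]
  pool <- new_trna_pool(tgcn, code)
  n_written <- NA_integer_
  if (!is.null(path)) {
    rows <- list()
    i <- 0L
    emit <- function(isotype, anticodon, note = "") {
      i <<- i + 1L
      sprintf("chr1\t%d\t%d\t%d\t%s\t%s\t0\t0\t%.1f%s",
              i, i * 100L, i * 100L + 72L, isotype, anticodon,
              70 + stats::runif(1, -5, 5),
              if (nzchar(note)) paste0("\t", note) else "")
    }
    for (ac in names(tgcn)) {
      iso <- code$codon_to_aa[revcomp(ac)]
      for (k in seq_len(tgcn[[ac]])) rows <- c(rows, emit(iso, ac))
    }
    for (k in seq_len(n_pseudo)) {
      ac <- sample(names(tgcn), 1L)
      rows <- c(rows, emit(code$codon_to_aa[revcomp(ac)], ac, "pseudo"))
    }
    for (k in seq_len(n_mismatch)) {
      ac <- sample(names(tgcn), 1L)
      right <- code$codon_to_aa[revcomp(ac)]
      wrong <- sample(setdiff(STANDARD_ISOTYPES, right), 1L)
      rows <- c(rows, emit(wrong, ac))
    }
    header <- c(
      "Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\t\tInf",
      "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore\tNote",
      "--------\t------\t-----\t----\t----\t-----\t-----\t----\t------\t----")
    writeLines(c(header, unlist(rows)), path)
    n_written <- length(rows)
  }
  list(pool = pool, path = if (is.null(path)) NA_character_ else path,
       n_records_written = n_written)
}

#' Simulate a coding-sequence set under mutation bias and selection
#'
#' Draws, for every gene g and amino-acid slot, a codon with probability
#' proportional to \eqn{m(c) \exp(\sigma \phi_g w_c)}: a multiplicative mix
#' of a GC3 mutational weight m (every G/C-ending codon weighted
#' \code{gc3_bias}, every A/T-ending codon \code{1 - gc3_bias}, normalized
#' within the synonymous family) and an expression-weighted preference for
#' high-adaptiveness codons.  Expression
#' levels \eqn{\phi_g} are lognormal(meanlog 0, sdlog 1) by default; the
#' amino-acid sequence of each gene is drawn uniformly over the 20 amino
#' acids unless a composition is supplied.  Gene lengths (in codons) are
#' lognormal around 400 codons, the typical scale of a yeast CDS.
#'
#' @param n_genes number of genes (default 2000)
#' @param mean_length mean gene length in codons (default 400)
#' @param length_sdlog lognormal sdlog of gene length (default 0.25)
#' @param code a \code{genetic_code}
#' @param gc3_bias probability a neutral draw takes a G/C-ending codon
#' @param selection_strength sigma >= 0
#' @param tgcn anticodon pool for adaptiveness (default
#'   \code{\link{skewed_anticodon_pool}})
#' @param aa_composition named probabilities over the 20 amino acids
#' @param phi optional expression levels (default lognormal draws)
#' @param path optional FASTA output path
#' @param seed RNG seed
#' @return list with \code{sequences} (named character, includes start ATG
#'   and a terminal stop), \code{phi}, \code{adaptiveness} (NULL when sigma
#'   is 0), and \code{params} (the full manifest)
#' @export
simulate_cds_set <- function(n_genes = 2000L, mean_length = 400L,
                             length_sdlog = 0.25,
                             code = get_code("standard"),
                             gc3_bias = 0.5, selection_strength = 0,
                             tgcn = skewed_anticodon_pool(code),
                             aa_composition = NULL, phi = NULL,
                             path = NULL, seed = 1L) {
  stopifnot(gc3_bias >= 0, gc3_bias <= 1, selection_strength >= 0)
  set.seed(substream_seed(seed, "cds"))
  aas <- names(code$degeneracy)
  if (is.null(aa_composition))
    aa_composition <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  adapt <- NULL
  w <- NULL
  if (selection_strength > 0) {
    pool <- new_trna_pool(tgcn, code)
    adapt <- build_adaptiveness(pool, wobble_rules(), code)
    w <- adapt$w
  }
  if (is.null(phi))
    phi <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  lengths <- pmax(10L, round(stats::rlnorm(
    n_genes, meanlog = log(mean_length) - length_sdlog^2 / 2,
    sdlog = length_sdlog)))
  # per-codon mutational weight by third-base class, normalized within the
  # family when drawing; beta = 0.5 makes every family uniform
  fam_list <- lapply(aas, function(a) codons_for_aa(a, code))
  names(fam_list) <- aas
  m_weights <- lapply(fam_list, function(fam) {
    third_gc <- substr(fam, 3L, 3L) %in% c("G", "C")
    stats::setNames(ifelse(third_gc, gc3_bias, 1 - gc3_bias), fam)
  })
  stops <- code$stop_codons
  seqs <- character(n_genes)
  for (g in seq_len(n_genes)) {
    L <- lengths[g]
    aa_seq <- sample(aas, L, replace = TRUE, prob = aa_composition)
    codons <- character(L)
    for (a in unique(aa_seq)) {
      slots <- which(aa_seq == a)
      fam <- fam_list[[a]]
      p <- m_weights[[a]]
      if (!is.null(w))
        p <- p * exp(selection_strength * phi[g] * w[fam])
      codons[slots] <- if (length(fam) == 1L) fam
        else sample(fam, length(slots), replace = TRUE, prob = p)
    }
    seqs[g] <- paste0("ATG", paste(codons, collapse = ""), stops[1L])
  }
  names(seqs) <- sprintf("gene%05d", seq_len(n_genes))
  if (!is.null(path)) {
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
  }
  list(sequences = seqs, phi = phi, adaptiveness = adapt,
       params = list(n_genes = n_genes, mean_length = mean_length,
                     length_sdlog = length_sdlog, code_id = code$code_id,
                     gc3_bias = gc3_bias,
                     selection_strength = selection_strength,
                     tgcn = tgcn, seed = seed))
}

.fitch3_bruteforce <- function(a, b, o) {
  # enumerate internal/root labelings over the observed states; returns the
  # minimal-change root states (outgroup-preferred tie-break applied later)
  states <- unique(c(a, b, o))
  best <- Inf
  roots <- character(0)
  for (root in states) for (node in states) {
    cost <- (root != node) + (node != a) + (node != b) + (root != o)
    if (cost < best) { best <- cost; roots <- root }
    else if (cost == best) roots <- union(roots, root)
  }
  list(roots = roots, cost = best)
}

#' Simulate ortholog families with planted conserved-arginine sites
#'
#' Builds gapless protein alignments over three taxon groups (two ingroups
#' and an outgroup) with CDSs that back-translate exactly.  Planted sites
#' are arginine in every taxon; each group carries a specified codon at a
#' specified within-group fraction (remaining members get a different
#' synonymous arginine codon, placed deterministically).  Non-planted
#' columns are drawn from non-arginine residues so that the planted site set
#' is exactly the arginine-conserved set.  The truth manifest records, for
#' every planted site, the per-group codons, the intended ancestral codon
#' (computed by brute-force parsimony enumeration, outgroup-preferred at
#' ties), and the per-ingroup-branch descendant codons.
#'
#' @param n_families number of ortholog families
#' @param group_sizes named integer, group id to taxon count; the first two
#'   ids are the ingroups, the third the outgroup
#' @param protein_length columns per family
#' @param planted either NULL (one default site per family cycling through
#'   canonical AGA/CGT patterns) or a data.frame with columns \code{family},
#'   \code{column}, one codon column per group id, and optional per-group
#'   fraction columns \code{frac_<group>} (default 1)
#' @param noise_rate per-taxon substitution rate at non-planted columns
#' @param code a \code{genetic_code}
#' @param seed RNG seed
#' @return list with \code{families} (list of lists: \code{protein_alignment},
#'   \code{cds}, \code{ortholog_id}), \code{groups} (named character, taxon
#'   to group), \code{topology}, and \code{truth} (data.frame)
#' @export
simulate_ortholog_families <- function(n_families = 6L,
                                       group_sizes = c(A = 8L, B = 8L, O = 8L),
                                       protein_length = 60L,
                                       planted = NULL, noise_rate = 0.05,
                                       code = get_code("standard"),
                                       seed = 1L) {
  set.seed(substream_seed(seed, "ortholog"))
  gids <- names(group_sizes)
  stopifnot(length(gids) == 3L)
  taxa <- unlist(lapply(gids, function(g)
    sprintf("%s_t%02d", g, seq_len(group_sizes[[g]]))))
  groups <- stats::setNames(rep(gids, times = group_sizes), taxa)
  if (is.null(planted)) {
    patterns <- list(c("AGA", "AGA", "AGA"), c("AGA", "AGA", "CGT"),
                     c("AGA", "CGT", "CGT"), c("CGT", "CGT", "CGT"))
    planted <- do.call(rbind, lapply(seq_len(n_families), function(f) {
      pat <- patterns[[(f - 1L) %% length(patterns) + 1L]]
      df <- data.frame(family = f, column = 10L, stringsAsFactors = FALSE)
      for (j in 1:3) df[[gids[j]]] <- pat[j]
      df
    }))
  }
  for (g in gids) {
    fc <- paste0("frac_", g)
    if (!fc %in% names(planted)) planted[[fc]] <- 1
  }
  non_r <- setdiff(names(code$degeneracy), "Arg")
  truth_rows <- list()
  families <- list()
  for (f in seq_len(n_families)) {
    sites <- planted[planted$family == f, , drop = FALSE]
    prot <- matrix("", nrow = length(taxa), ncol = protein_length,
                   dimnames = list(taxa, NULL))
    codon_mat <- matrix("", nrow = length(taxa), ncol = protein_length,
                        dimnames = list(taxa, NULL))
    for (col in seq_len(protein_length)) {
      if (col %in% sites$column) next
      base_aa <- sample(non_r, 1L)
      col_aa <- rep(base_aa, length(taxa))
      flip <- stats::runif(length(taxa)) < noise_rate
      col_aa[flip] <- sample(non_r, sum(flip), replace = TRUE)
      for (i in seq_along(taxa)) {
        fam <- codons_for_aa(col_aa[i], code)
        codon_mat[i, col] <- if (length(fam) == 1L) fam
                             else sample(fam, 1L)
        prot[i, col] <- AA_ONE[[col_aa[i]]]
      }
    }
    for (sidx in seq_len(nrow(sites))) {
      col <- sites$column[sidx]
      prot[, col] <- "R"
      for (g in gids) {
        members <- taxa[groups == g]
        consensus <- sites[[g]][sidx]
        frac <- sites[[paste0("frac_", g)]][sidx]
        k <- round(frac * length(members))
        alt <- setdiff(ARG_CODONS, consensus)[1L]
        codon_mat[members, col] <- c(rep(consensus, k),
                                     rep(alt, length(members) - k))
      }
      fit <- .fitch3_bruteforce(sites[[gids[1]]][sidx],
                                sites[[gids[2]]][sidx],
                                sites[[gids[3]]][sidx])
      anc <- if (sites[[gids[3]]][sidx] %in% fit$roots)
        sites[[gids[3]]][sidx] else fit$roots[1L]
      tr <- data.frame(family = f, column = col,
                       ancestral = anc, stringsAsFactors = FALSE)
      for (j in 1:3) tr[[gids[j]]] <- sites[[gids[j]]][sidx]
      truth_rows <- c(truth_rows, list(tr))
    }
    protein_alignment <- apply(prot, 1L, paste, collapse = "")
    cds <- apply(codon_mat, 1L, paste, collapse = "")
    families[[f]] <- list(ortholog_id = sprintf("og%04d", f),
                          protein_alignment = protein_alignment,
                          cds = cds)
  }
  list(families = families, groups = groups, topology = gids,
       truth = do.call(rbind, truth_rows))
}

#' Simulate a pure-birth tree with correlated Brownian traits
#'
#' Generates a Yule tree, a Brownian predictor x, and a response
#' \eqn{y = a + b x + e} where e is Brownian noise; both x and e covary
#' according to the tree covariance with off-diagonals scaled by lambda.
#'
#' @param n_tips number of tips (>= 4)
#' @param b true slope
#' @param a true intercept
#' @param lambda Pagel's lambda of the trait covariance
#' @param sigma_x,sigma_e Brownian rates of predictor and noise
#' @param seed RNG seed
#' @return list with \code{tree} (ape::phylo), \code{traits} (data.frame
#'   with rownames = tip labels, columns x and y), and \code{truth}
#' @export
simulate_tree_and_traits <- function(n_tips, b = 0.5, a = 0, lambda = 1,
                                     sigma_x = 1, sigma_e = 0.25,
                                     seed = 1L) {
  stopifnot(n_tips >= 4L)
  set.seed(substream_seed(seed, "tree"))
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  V <- .lambda_vcv(ape::vcv(tree), lambda)
  x <- MASS::mvrnorm(1, mu = rep(0, n_tips), Sigma = sigma_x^2 * V)
  e <- MASS::mvrnorm(1, mu = rep(0, n_tips), Sigma = sigma_e^2 * V)
  y <- a + b * x + e
  traits <- data.frame(x = x, y = y, row.names = tree$tip.label)
  list(tree = tree, traits = traits,
       truth = list(a = a, b = b, lambda = lambda, sigma_x = sigma_x,
                    sigma_e = sigma_e, seed = seed))
}
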