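#' Wobble-pairing rule set for codon adaptiveness
#'
#' Each rule pairs a codon third base with an anticodon first base
#' (DNA convention) under a selective penalty s in [0, 1]; Watson-Crick
#' pairs carry s = 0.  The defaults are the eukaryotic constants of the
#' classical tAI construction: G:U wobble (codon-3rd T read by anticodon-1st
#' G, s = 0.41), inosine pairing of A-first-base anticodons with C-ending
#' (s = 0.28) and A-ending codons (s = 0.9999), and U:G wobble (codon-3rd G
#' read by anticodon-1st T, s = 0.68).  The prokaryote-specific lysidine
#' pairing (C-first-base anticodon reading ATA, s = 0.89) is off by default.
#'
#' @param s_gu,s_ic,s_ia,s_ug wobble penalties (defaults above)
#' @param prokaryote include the lysidine rule for codon ATA
#' @param s_lysidine penalty for the lysidine rule
#' @param mode \code{"box"} (mechanical pairing within the codon box) or
#'   \code{"isotype_restricted"} (a recognizing anticodon contributes only
#'   when its Watson-Crick codon encodes the same amino acid as the codon
#'   being read; this is the only mode in which a reassigned-clade Ser-CAG
#'   anticodon feeds CTG rather than the leucine box)
#' @return object of class \code{wobble_rules}: data.frame of
#'   (codon3, anticodon1, s, label) plus attributes
#' @export
wobble_rules <- function(s_gu = 0.41, s_ic = 0.28, s_ia = 0.9999,
                         s_ug = 0.68, prokaryote = FALSE,
                         s_lysidine = 0.89,
                         mode = c("box", "isotype_restricted")) {
  mode <- match.arg(mode)
  df <- data.frame(
    codon3    = c("T", "T", "C", "C", "A", "A", "G", "G"),
    anticodon1 = c("A", "G", "G", "A", "T", "A", "C", "T"),
    s = c(0, s_gu, 0, s_ic, 0, s_ia, 0, s_ug),
    label = c("WC A:U", "G:U wobble", "WC G:C", "I:C", "WC U:A", "I:A",
              "WC C:G", "U:G wobble"),
    stringsAsFactors = FALSE
  )
  stopifnot(all(df$s >= 0 & df$s <= 1))
  structure(df, class = c("wobble_rules", "data.frame"),
            mode = mode, prokaryote = prokaryote, s_lysidine = s_lysidine)
}

#' Absolute codon adaptiveness W from a tRNA pool
#'
#' For each sense codon i, \eqn{W_i = \sum_j (1 - s_j)\, tGCN_j} over the
#' anticodons j that recognize it: positions 2-3 of the anticodon must be
#' the Watson-Crick complement of codon positions 1-2, and the
#' (codon-3rd base, anticodon-1st base) pair must appear in the rule set.
#'
#' @param pool a \code{trna_pool}
#' @param rules a \code{wobble_rules}
#' @param code a \code{genetic_code}
#' @return named numeric vector of W over the code's sense codons
#' @export
codon_absolute_adaptiveness <- function(pool, rules, code) {
  mode <- attr(rules, "mode")
  W <- stats::setNames(numeric(length(code$sense_codons)), code$sense_codons)
  for (cod in code$sense_codons) {
    wc_anticodon <- revcomp(cod)
    tail23 <- substr(wc_anticodon, 2L, 3L)
    c3 <- substr(cod, 3L, 3L)
    hits <- rules[rules$codon3 == c3, , drop = FALSE]
    for (r in seq_len(nrow(hits))) {
      ac <- paste0(hits$anticodon1[r], tail23)
      copies <- pool$tgcn[ac]
      if (is.na(copies) || copies == 0L) next
      if (mode == "isotype_restricted") {
        ac_aa <- code$codon_to_aa[revcomp(ac)]
        if (is.na(ac_aa) || ac_aa != code$codon_to_aa[cod]) next
      }
      W[cod] <- W[cod] + (1 - hits$s[r]) * copies
    }
    if (isTRUE(attr(rules, "prokaryote")) && cod == "ATA") {
      copies <- pool$tgcn["CAT"]
      if (!is.na(copies))
        W[cod] <- W[cod] + (1 - attr(rules, "s_lysidine")) * copies
    }
  }
  W
}

#' Relative codon adaptiveness table
#'
#' Scales absolute adaptiveness to \eqn{w_i = W_i / \max W}; codons with no
#' recognizing anticodon (W = 0) receive the geometric mean of the nonzero
#' w values, and are recorded so downstream users can see which codons
#' (e.g. CGN in a genome lacking CGN-decoding tRNAs) are imputed rather
#' than measured.
#'
#' @param pool a \code{trna_pool}
#' @param rules a \code{wobble_rules} (default eukaryotic box rules)
#' @param code a \code{genetic_code}
#' @return object of class \code{adaptiveness}: list with \code{W}, \code{w},
#'   \code{zero_W_codons}, \code{code_id}, \code{mode}
#' @export
build_adaptiveness <- function(pool, rules = wobble_rules(),
                               code = get_code(pool$code_id)) {
  W <- codon_absolute_adaptiveness(pool, rules, code)
  if (all(W == 0)) stop("no decoding capacity: all W are zero")
  w <- W / max(W)
  zero <- names(w)[w == 0]
  if (length(zero) > 0) {
    gm <- exp(mean(log(w[w > 0])))
    w[zero] <- gm
  }
  structure(list(W = W, w = w, zero_W_codons = zero,
                 code_id = code$code_id, mode = attr(rules, "mode")),
            class = "adaptiveness")
}

#' @export
print.adaptiveness <- function(x, ...) {
  cat("Codon adaptiveness (", x$mode, " mode, code ", x$code_id, "): ",
      length(x$w), " sense codons, ", length(x$zero_W_codons),
      " imputed by geometric-mean fallback\n", sep = "")
  invisible(x)
}

#' tRNA adaptation index of a gene
#'
#' Geometric mean of relative codon adaptiveness over the gene's sense
#' codons: \eqn{tAI = \exp(\sum_i n_i \log w_i / \sum_i n_i)}.  Stop codons
#' never contribute; Met's ATG contributes like any sense codon.
#'
#' @param counts a \code{codon_counts} table
#' @param adapt an \code{adaptiveness} table on the same code
#' @return tAI in (0, 1]
#' @export
gene_tai <- function(counts, adapt) {
  stopifnot(counts$code_id == adapt$code_id)
  n <- counts$counts[names(adapt$w)]
  total <- sum(n)
  if (total == 0L) stop("no sense codons counted")
  exp(sum(n * log(adapt$w)) / total)
}

#' Genome-level S-value of translational selection
#'
#' Per gene, the deviation of the observed effective number of codons from
#' its composition-only expectation is
#' \eqn{(Nc^{exp}(GC3s) - Nc) / Nc^{exp}(GC3s)}; the S-value is the
#' correlation between tAI and this deviation across genes.  S near 1 means
#' genes whose codons match the tRNA pool are exactly the genes whose Nc
#' falls furthest below the mutational null: translational selection.  Genes
#' with undefined tAI, Nc or GC3s are dropped and counted.
#'
#' @param gene_stats data.frame with columns \code{tai}, \code{nc},
#'   \code{gc3s} (one row per gene)
#' @param method correlation type, \code{"pearson"} (default) or
#'   \code{"spearman"}
#' @return object of class \code{selection_report}: list with
#'   \code{s_value}, \code{n_genes} used, \code{n_dropped},
#'   \code{undefined_reason} (NA unless s_value is NA), \code{method},
#'   and \code{per_gene} (the usable rows with \code{nc_deviation} added)
#' @export
s_value <- function(gene_stats, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(all(c("tai", "nc", "gc3s") %in% names(gene_stats)))
  ok <- stats::complete.cases(gene_stats[, c("tai", "nc", "gc3s")])
  rows <- gene_stats[ok, , drop = FALSE]
  rows$nc_deviation <- (expected_nc(rows$gc3s) - rows$nc) /
    expected_nc(rows$gc3s)
  s <- NA_real_
  reason <- NA_character_
  if (nrow(rows) < 3L) {
    reason <- "fewer than 3 usable genes"
  } else if (stats::var(rows$tai) == 0 || stats::var(rows$nc_deviation) == 0) {
    reason <- "zero variance in tai or nc_deviation"
  } else {
    s <- stats::cor(rows$tai, rows$nc_deviation, method = method)
  }
  structure(list(s_value = s, n_genes = nrow(rows),
                 n_dropped = sum(!ok), undefined_reason = reason,
                 method = method, per_gene = rows),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  if (is.na(x$s_value)) {
    cat("S-value: undefined (", x$undefined_reason, "); ", x$n_genes,
        " usable genes, ", x$n_dropped, " dropped\n", sep = "")
  } else {
    cat(sprintf("S-value: %.3f (%s, %d genes, %d dropped)\n",
                x$s_value, x$method, x$n_genes, x$n_dropped))
  }
  invisible(x)
}

#' Per-gene selection statistics for a set of coding sequences
#'
#' Convenience composition: codon counts, tAI, Nc and GC3s for every gene,
#' ready for \code{\link{s_value}}.
#'
#' @param counts_list list of \code{codon_counts}
#' @param adapt an \code{adaptiveness} table
#' @param code a \code{genetic_code}
#' @return data.frame with \code{seq_id}, \code{tai}, \code{nc}, \code{gc3s},
#'   \code{gc}, \code{gc3}, \code{length_codons}
#' @export
genome_selection_stats <- function(counts_list, adapt,
                                   code = get_code(adapt$code_id)) {
  rows <- lapply(counts_list, function(cc) {
    st <- gene_codon_stats(cc, code)
    st$tai <- gene_tai(cc, adapt)
    st
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("seq_id", "tai", "nc", "gc3s", "gc", "gc3", "length_codons")]
}
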