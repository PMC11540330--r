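#' Count frame-0 codons in a coding sequence
#'
#' Codons containing ambiguity characters (anything outside ACGT) are
#' excluded from the counts and from the total; a terminal stop codon is
#' counted but flagged separately from the sense total.
#'
#' @param cds DNA string, length divisible by 3
#' @param code a \code{genetic_code}
#' @param seq_id optional label carried in the result
#' @return object of class \code{codon_counts}: list with \code{seq_id},
#'   \code{counts} (named integer over the 64 codons), \code{total_sense}
#'   (sense codons counted), \code{stop_count}, \code{dropped} (ambiguous
#'   codons excluded), and \code{code_id}.
#' @examples
#' cc <- count_codons("ATGGTTGTTTAA", get_code("standard"))
#' cc$counts[["GTT"]]  # 2
#' @export
count_codons <- function(cds, code, seq_id = NA_character_) {
  codons <- .split_codons(toupper(cds))
  known <- codons %in% all_codons()
  counts <- stats::setNames(integer(64), all_codons())
  tab <- table(codons[known])
  counts[names(tab)] <- as.integer(tab)
  new_codon_counts(counts, code, seq_id = seq_id,
                   dropped = sum(!known))
}

#' Assemble a codon-count table from a named count vector
#'
#' Low-level constructor used by \code{\link{count_codons}} and by code that
#' builds count tables directly (e.g. worked examples or pooled tables).
#'
#' @param counts named integer vector; names must be codons
#' @param code a \code{genetic_code}
#' @param seq_id optional label
#' @param dropped number of ambiguous codons excluded upstream
#' @return a \code{codon_counts} object
#' @export
new_codon_counts <- function(counts, code, seq_id = NA_character_,
                             dropped = 0L) {
  full <- stats::setNames(integer(64), all_codons())
  if (!all(names(counts) %in% all_codons()))
    stop("unknown codon name(s): ",
         paste(setdiff(names(counts), all_codons()), collapse = ", "))
  full[names(counts)] <- as.integer(counts)
  structure(list(
    seq_id = seq_id,
    counts = full,
    total_sense = sum(full[code$sense_codons]),
    stop_count = sum(full[code$stop_codons]),
    dropped = as.integer(dropped),
    code_id = code$code_id
  ), class = "codon_counts")
}

#' Add two codon count tables
#' @param e1,e2 \code{codon_counts} on the same code
#' @return pooled \code{codon_counts}
#' @export
"+.codon_counts" <- function(e1, e2) {
  stopifnot(e1$code_id == e2$code_id)
  new_codon_counts(e1$counts + e2$counts, get_code(e1$code_id),
                   seq_id = NA_character_,
                   dropped = e1$dropped + e2$dropped)
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("Codon counts", if (!is.na(x$seq_id)) paste0(" [", x$seq_id, "]"),
      ": ", x$total_sense, " sense, ", x$stop_count, " stop, ",
      x$dropped, " ambiguous dropped (code ", x$code_id, ")\n", sep = "")
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' RSCU for codon c of amino acid a with k synonymous codons is
#' \eqn{k \cdot n_c / \sum_{c' \in a} n_{c'}}: the observed count divided by
#' the count expected if usage within the family were uniform.  With 100
#' valine codons of which 60 are GTT, RSCU(GTT) = 4 * 60/100 = 2.4.  Codons
#' of amino acids absent from the input are reported as undefined (NA), not
#' zero.  Only degenerate codons (family size >= 2) carry RSCU values; stop
#' codons never contribute.
#'
#' @param counts a \code{codon_counts} table (per-gene or pooled)
#' @param code a \code{genetic_code} (defaults to the table's code)
#' @return object of class \code{rscu_profile}: list with \code{values}
#'   (named numeric over the degenerate codons, NA where undefined),
#'   \code{undefined_codons}, \code{scope = "gene"}, \code{code_id}.
#' @export
rscu <- function(counts, code = get_code(counts$code_id)) {
  stopifnot(inherits(counts, "codon_counts"))
  vals <- stats::setNames(rep(NA_real_, length(code$degenerate_codons)),
                          code$degenerate_codons)
  for (aa in names(code$degeneracy)[code$degeneracy >= 2L]) {
    fam <- codons_for_aa(aa, code)
    n_fam <- sum(counts$counts[fam])
    if (n_fam > 0L)
      vals[fam] <- code$degeneracy[[aa]] * counts$counts[fam] / n_fam
  }
  structure(list(
    scope = "gene",
    seq_id = counts$seq_id,
    values = vals,
    undefined_codons = names(vals)[is.na(vals)],
    code_id = code$code_id
  ), class = "rscu_profile")
}

#' @export
print.rscu_profile <- function(x, ...) {
  cat("RSCU profile (", x$scope, " scope, code ", x$code_id, "): ",
      sum(!is.na(x$values)), " defined / ", length(x$values),
      " degenerate codons\n", sep = "")
  invisible(x)
}

#' Genome-wide average RSCU
#'
#' Per-codon unweighted mean over gene-level profiles; genes in which a
#' codon's amino acid is absent (undefined RSCU) are excluded from that
#' codon's mean rather than entering as zero.  A pooled-counts mode is
#' available for sensitivity analysis: there, counts are summed over genes
#' before a single RSCU computation, which weights genes by length.
#'
#' @param gene_profiles list of \code{rscu_profile} (mean-of-genes mode) or,
#'   when \code{method = "pooled"}, list of \code{codon_counts}
#' @param method \code{"mean"} (default) or \code{"pooled"}
#' @return an \code{rscu_profile} with \code{scope = "genome"} and, in mean
#'   mode, an \code{n_genes} vector giving the per-codon number of genes used
#' @export
genome_average_rscu <- function(gene_profiles, method = c("mean", "pooled")) {
  method <- match.arg(method)
  stopifnot(length(gene_profiles) >= 1L)
  if (method == "pooled") {
    pooled <- Reduce(`+`, gene_profiles)
    prof <- rscu(pooled)
    prof$scope <- "genome"
    return(prof)
  }
  code_ids <- unique(vapply(gene_profiles, `[[`, character(1), "code_id"))
  stopifnot(length(code_ids) == 1L)
  mat <- do.call(rbind, lapply(gene_profiles, `[[`, "values"))
  vals <- colMeans(mat, na.rm = TRUE)
  n_used <- colSums(!is.na(mat))
  vals[n_used == 0L] <- NA_real_
  structure(list(
    scope = "genome",
    seq_id = NA_character_,
    values = vals,
    n_genes = n_used,
    undefined_codons = names(vals)[is.na(vals)],
    code_id = code_ids
  ), class = "rscu_profile")
}

.codon_base_at <- function(codons, pos) substr(codons, pos, pos)

#' Per-gene GC statistics and effective number of codons
#'
#' \code{gc} is the G+C fraction over all positions of counted sense codons;
#' \code{gc3} restricts to third positions of sense codons; \code{gc3s}
#' restricts further to synonymous third positions: codons whose third base
#' can be substituted without changing the encoded amino acid (some codon
#' with the same first two bases encodes the same residue).  Under the
#' standard code this excludes exactly Met, Trp and stops (the classic
#' 59-codon set); under the CTG-reassigned codes, CTG is additionally
#' excluded because its third-position neighbours encode leucine while CTG
#' itself does not.  Statistics with zero eligible positions are NA, not 0.
#'
#' @param counts a \code{codon_counts} table
#' @param code a \code{genetic_code}
#' @param min_codons genes shorter than this many sense codons are flagged
#'   unstable (Nc on very short genes is reported but unreliable)
#' @return data.frame with one row: \code{seq_id}, \code{gc}, \code{gc3},
#'   \code{gc3s}, \code{nc}, \code{length_codons}, \code{short_flag}
#' @export
gene_codon_stats <- function(counts, code = get_code(counts$code_id),
                             min_codons = 30L) {
  n <- counts$counts[code$sense_codons]
  total <- sum(n)
  gc <- if (total > 0) {
    per_codon_gc <- vapply(code$sense_codons, function(cd)
      sum(strsplit(cd, "")[[1]] %in% c("G", "C")), numeric(1))
    sum(per_codon_gc * n) / (3 * total)
  } else NA_real_
  third <- .codon_base_at(code$sense_codons, 3L)
  gc3 <- if (total > 0) sum(n[third %in% c("G", "C")]) / total else NA_real_
  syn3 <- synonymous_third_codons(code)
  n_syn <- counts$counts[syn3]
  total_syn <- sum(n_syn)
  third_syn <- .codon_base_at(syn3, 3L)
  gc3s <- if (total_syn > 0)
    sum(n_syn[third_syn %in% c("G", "C")]) / total_syn else NA_real_
  data.frame(
    seq_id = counts$seq_id,
    gc = gc, gc3 = gc3, gc3s = gc3s,
    nc = effective_number_of_codons(counts, code),
    length_codons = total,
    short_flag = total < min_codons,
    stringsAsFactors = FALSE
  )
}

#' Effective number of codons (Nc), generalized Wright estimator
#'
#' For each amino acid a with \eqn{n_a \ge 2} observed codons, the codon
#' homozygosity is \eqn{F_a = (n_a \sum_i p_i^2 - 1) / (n_a - 1)} with
#' \eqn{p_i} the within-family codon frequencies.  F is averaged within each
#' degeneracy class k >= 2 (amino acids with \eqn{n_a < 2} or \eqn{F_a \le 0}
#' are skipped), and
#' \deqn{N_c = N_1 + \sum_k m_k / \bar F_k}
#' where \eqn{N_1} is the number of nondegenerate amino acids and \eqn{m_k}
#' the number of amino acids in class k.  A class with no estimable
#' \eqn{\bar F} is imputed as the mean of adjacent estimable classes
#' (the classical convention for the 3-fold isoleucine class); the estimate
#' is capped at the number of sense codons.  Generalizing over classes makes
#' the estimator valid for reassigned codes (e.g. 7-fold serine under the
#' CTG-Ser code).
#'
#' @param counts a \code{codon_counts} table
#' @param code a \code{genetic_code}
#' @return Nc as a single numeric, or NA when no class is estimable
#' @export
effective_number_of_codons <- function(counts,
                                       code = get_code(counts$code_id)) {
  deg <- code$degeneracy
  classes <- sort(unique(deg[deg >= 2L]))
  n1 <- sum(deg == 1L)
  f_by_class <- stats::setNames(rep(NA_real_, length(classes)),
                                as.character(classes))
  m_by_class <- stats::setNames(integer(length(classes)),
                                as.character(classes))
  for (k in classes) {
    aas <- names(deg)[deg == k]
    m_by_class[[as.character(k)]] <- length(aas)
    fs <- c()
    for (aa in aas) {
      fam <- codons_for_aa(aa, code)
      n_a <- sum(counts$counts[fam])
      if (n_a < 2L) next
      p <- counts$counts[fam] / n_a
      f <- (n_a * sum(p^2) - 1) / (n_a - 1)
      if (f > 0) fs <- c(fs, f)
    }
    if (length(fs) > 0) f_by_class[[as.character(k)]] <- mean(fs)
  }
  if (all(is.na(f_by_class))) return(NA_real_)
  # impute empty classes as the mean of adjacent (by class order) estimable ones
  if (any(is.na(f_by_class))) {
    est_idx <- which(!is.na(f_by_class))
    for (i in which(is.na(f_by_class))) {
      below <- est_idx[est_idx < i]
      above <- est_idx[est_idx > i]
      neighbors <- c(if (length(below)) f_by_class[max(below)],
                     if (length(above)) f_by_class[min(above)])
      f_by_class[i] <- mean(neighbors)
    }
  }
  nc <- n1 + sum(m_by_class / f_by_class)
  min(nc, length(code$sense_codons))
}

#' Wright's expected Nc under GC3s alone
#'
#' Null curve for the effective number of codons when composition, not
#' selection, drives codon usage:
#' \deqn{N_c^{exp}(s) = 2 + s + 29 / (s^2 + (1 - s)^2)}
#' with s the synonymous third-position GC content.
#'
#' @param gc3s numeric vector in [0, 1]
#' @return expected Nc, same length
#' @export
expected_nc <- function(gc3s) {
  stopifnot(all(gc3s >= 0 & gc3s <= 1, na.rm = TRUE))
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Sense codons whose third position is synonymous
#'
#' A codon qualifies when at least one other codon sharing its first two
#' bases encodes the same amino acid, so a third-base substitution can be
#' silent.  Standard code: the 59 codons outside Met, Trp and stops.
#'
#' @param code a \code{genetic_code}
#' @return character vector of codons
#' @export
synonymous_third_codons <- function(code) {
  sense <- code$sense_codons
  prefix <- substr(sense, 1L, 2L)
  aa <- code$codon_to_aa[sense]
  keep <- vapply(seq_along(sense), function(i) {
    sib <- sense[prefix == prefix[i] & sense != sense[i]]
    any(code$codon_to_aa[sib] == aa[i])
  }, logical(1))
  sense[keep]
}

ARG_CODONS <- c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG")
CGN_CODONS <- c("CGT", "CGC", "CGA", "CGG")

#' Arginine codon census over a transcript set
#'
#' Summarizes arginine codon usage the way a transcriptome screen for CGN
#' avoidance does: overall fractions of each of the six arginine codons,
#' per-transcript CGN counts, the fraction of transcripts free of CGN, and
#' how many transcripts exceed a CGN-count threshold.
#'
#' @param transcript_counts list of \code{codon_counts}, one per transcript
#' @param cgn_threshold transcripts with more CGN codons than this are
#'   counted as CGN-rich (default 20)
#' @return list with \code{codon_fractions} (named over the six arginine
#'   codons), \code{total_arg}, \code{cgn_per_transcript}, \code{zero_cgn_fraction},
#'   \code{median_cgn}, \code{mean_cgn}, \code{n_over_threshold},
#'   \code{n_transcripts}
#' @export
arginine_codon_census <- function(transcript_counts, cgn_threshold = 20L) {
  if (length(transcript_counts) == 0L) stop("empty transcript set")
  mat <- do.call(rbind, lapply(transcript_counts,
                               function(x) x$counts[ARG_CODONS]))
  totals <- colSums(mat)
  total_arg <- sum(totals)
  cgn <- rowSums(mat[, CGN_CODONS, drop = FALSE])
  list(
    codon_fractions = if (total_arg > 0) totals / total_arg
                      else stats::setNames(rep(NA_real_, 6L), ARG_CODONS),
    total_arg = total_arg,
    cgn_per_transcript = as.integer(cgn),
    zero_cgn_fraction = mean(cgn == 0),
    median_cgn = stats::median(cgn),
    mean_cgn = mean(cgn),
    n_over_threshold = sum(cgn > cgn_threshold),
    n_transcripts = length(transcript_counts)
  )
}

#' Read a CDS FASTA into codon count tables
#'
#' @param path multi-FASTA of coding sequences
#' @param code a \code{genetic_code}
#' @param skip_bad skip (with a warning) records whose length is not a
#'   multiple of 3 instead of erroring
#' @return named list of \code{codon_counts}
#' @export
read_cds_counts <- function(path, code, skip_bad = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    s <- as.character(seqs[[i]])
    if (nchar(s) %% 3L != 0L) {
      if (skip_bad) {
        warning("skipping '", id, "': length not divisible by 3")
        next
      }
      stop("record '", id, "': length not divisible by 3")
    }
    out[[id]] <- count_codons(s, code, seq_id = id)
  }
  out
}
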