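# shared fixtures and independent oracles

std <- get_code("standard")

# random in-frame CDS without internal stops (terminal stop optional)
random_cds <- function(n_codons, code = std, stop_tail = FALSE) {
  body <- sample(code$sense_codons, n_codons, replace = TRUE)
  paste0(paste(body, collapse = ""),
         if (stop_tail) code$stop_codons[1] else "")
}

# brute-force codon tally, independent of count_codons
oracle_codon_tally <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  table(codons[codons %in% cubevol::all_codons()])
}

# independent homozygosity-based Nc on the standard code
oracle_nc <- function(counts_vec, code = std) {
  f_class <- list()
  for (aa in names(code$degeneracy)) {
    k <- code$degeneracy[[aa]]
    if (k < 2) next
    fam <- codons_for_aa(aa, code)
    n_a <- sum(counts_vec[fam])
    if (n_a < 2) next
    p <- counts_vec[fam] / n_a
    f <- (n_a * sum(p^2) - 1) / (n_a - 1)
    if (f > 0) f_class[[as.character(k)]] <- c(f_class[[as.character(k)]], f)
  }
  ks <- sort(unique(code$degeneracy[code$degeneracy >= 2]))
  fbar <- sapply(as.character(ks), function(k)
    if (is.null(f_class[[k]])) NA_real_ else mean(f_class[[k]]))
  # adjacency imputation
  for (i in which(is.na(fbar))) {
    est <- which(!is.na(fbar))
    lo <- est[est < i]; hi <- est[est > i]
    fbar[i] <- mean(c(if (length(lo)) fbar[max(lo)],
                      if (length(hi)) fbar[min(hi)]))
  }
  m <- sapply(ks, function(k) sum(code$degeneracy == k))
  min(sum(code$degeneracy == 1) + sum(m / fbar), length(code$sense_codons))
}

# reference tAI adaptiveness construction: loop over the 16 codon boxes in
# T/C/A/G order exactly as the classical implementation does
oracle_tai_ws <- function(tgcn_by_anticodon, s = c(gu = 0.41, ic = 0.28,
                                                   ia = 0.9999, ug = 0.68)) {
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(as.vector(outer(b, b, paste0)), b, paste0)))
  trna <- sapply(codons, function(cod) {
    x <- tgcn_by_anticodon[cubevol::revcomp(cod)]
    if (is.na(x)) 0 else x
  })
  p <- 1 - c(0, 0, 0, 0, s[["gu"]], s[["ic"]], s[["ia"]], s[["ug"]])
  W <- numeric(64)
  for (i in seq(1, 61, by = 4)) {
    W[i]     <- p[1] * trna[i]     + p[5] * trna[i + 1]  # NNT
    W[i + 1] <- p[2] * trna[i + 1] + p[6] * trna[i]      # NNC
    W[i + 2] <- p[3] * trna[i + 2] + p[7] * trna[i]      # NNA
    W[i + 3] <- p[4] * trna[i + 3] + p[8] * trna[i + 2]  # NNG
  }
  stats::setNames(W, codons)
}

# dense-matrix GLS oracle: slope of y on x under covariance V
oracle_gls <- function(V, x, y) {
  X <- cbind(1, x)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  drop(beta)
}

counts_from_vec <- function(vec, code = std, seq_id = NA_character_) {
  new_codon_counts(vec, code, seq_id = seq_id)
}
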