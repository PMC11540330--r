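#' Parse tRNAscan-SE 2.x tabular output
#'
#' Reads the flat ".out" layout: three header lines followed by
#' whitespace-delimited columns (sequence name, tRNA number, begin, end,
#' isotype, anticodon, intron begin, intron end, score, and an optional note
#' column which carries the "pseudo" annotation).
#'
#' @param path path to a tRNAscan-SE tabular file
#' @return data.frame with columns \code{seq_name}, \code{trna_number},
#'   \code{begin}, \code{end}, \code{isotype}, \code{anticodon},
#'   \code{intron_begin}, \code{intron_end}, \code{score}, \code{note},
#'   \code{pseudo_flag}
#' @export
parse_trnascan <- function(path) {
  lines <- readLines(path)
  if (length(lines) >= 1L && grepl("^Sequence|^Name|^----", lines[1]))
    lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(seq_name = character(0), trna_number = integer(0),
                      begin = integer(0), end = integer(0),
                      isotype = character(0), anticodon = character(0),
                      intron_begin = integer(0), intron_end = integer(0),
                      score = numeric(0), note = character(0),
                      pseudo_flag = logical(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 9L)
      stop("malformed tRNAscan-SE line ", i + 3L, ": fewer than 9 fields")
    nums <- suppressWarnings(as.numeric(f[c(2, 3, 4, 7, 8, 9)]))
    if (any(is.na(nums)))
      stop("malformed tRNAscan-SE line ", i + 3L,
           ": non-numeric coordinate or score field")
    note <- if (length(f) > 9L) paste(f[10:length(f)], collapse = " ") else ""
    data.frame(seq_name = f[1], trna_number = as.integer(nums[1]),
               begin = as.integer(nums[2]), end = as.integer(nums[3]),
               isotype = f[5], anticodon = toupper(chartr("U", "T", f[6])),
               intron_begin = as.integer(nums[4]),
               intron_end = as.integer(nums[5]),
               score = nums[6], note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pseudo_flag <- grepl("pseudo", out$note, ignore.case = TRUE)
  out
}

STANDARD_ISOTYPES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu",
                       "Gly", "His", "Ile", "Leu", "Lys", "Met", "Phe",
                       "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")

#' Filter predicted tRNA genes into a per-anticodon gene-copy pool
#'
#' Applies the inventory filtering used for genomic tRNA pools: removes
#' pseudogenes, records lacking a standard isotype (Undet, Sup, SeC and the
#' like), records without a usable anticodon, and records whose anticodon
#' implies (by reverse complement under the active code) a different amino
#' acid than the predicted isotype.  Under the \code{ctg_ser}/\code{ctg_ala}
#' codes, Ser- or Ala-isotype tRNAs with the CAG anticodon are consistent
#' with the reassigned CTG codon and are retained; the same record under the
#' standard code is a mismatch and is removed.  All removals are logged with
#' reasons.
#'
#' @param records data.frame from \code{\link{parse_trnascan}}
#' @param code a \code{genetic_code} chosen per clade
#' @return object of class \code{trna_pool}: list with \code{tgcn} (named
#'   integer, anticodon to gene-copy count), \code{trnaome_size},
#'   \code{anticodon_type_count}, \code{removed} (data.frame of record index,
#'   isotype, anticodon, reason), and \code{code_id}
#' @export
filter_trnas <- function(records, code) {
  n <- nrow(records)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  mark <- function(i, why) {
    drop <- keep & i
    keep[drop] <<- FALSE
    reason[drop] <<- why
  }
  mark(records$pseudo_flag, "pseudogene")
  mark(!(records$isotype %in% STANDARD_ISOTYPES), "missing or non-standard isotype")
  has_ac <- records$anticodon %in% all_codons()
  mark(!has_ac, "missing anticodon")
  implied_codon <- rep(NA_character_, n)
  implied_codon[has_ac] <- anticodon_to_codon(records$anticodon[has_ac])
  implied_aa <- rep(NA_character_, n)
  implied_aa[has_ac] <- code$codon_to_aa[implied_codon[has_ac]]
  mark(!is.na(implied_aa) & implied_aa != records$isotype,
       "isotype/anticodon mismatch")
  kept <- records[keep, , drop = FALSE]
  tgcn_tab <- table(kept$anticodon)
  tgcn <- stats::setNames(as.integer(tgcn_tab), names(tgcn_tab))
  removed <- data.frame(
    index = which(!keep),
    isotype = records$isotype[!keep],
    anticodon = records$anticodon[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  structure(list(
    tgcn = tgcn,
    trnaome_size = sum(tgcn),
    anticodon_type_count = sum(tgcn > 0L),
    removed = removed,
    code_id = code$code_id
  ), class = "trna_pool")
}

#' Build a tRNA pool directly from gene-copy numbers
#'
#' @param tgcn named integer vector, anticodon (DNA convention) to copies
#' @param code a \code{genetic_code}
#' @return a \code{trna_pool}
#' @export
new_trna_pool <- function(tgcn, code) {
  stopifnot(all(names(tgcn) %in% all_codons()), all(tgcn >= 0))
  tgcn <- tgcn[tgcn > 0L]
  tgcn <- tgcn[order(names(tgcn))]
  structure(list(
    tgcn = stats::setNames(as.integer(tgcn), names(tgcn)),
    trnaome_size = sum(as.integer(tgcn)),
    anticodon_type_count = sum(tgcn > 0L),
    removed = data.frame(index = integer(0), isotype = character(0),
                         anticodon = character(0), reason = character(0),
                         stringsAsFactors = FALSE),
    code_id = code$code_id
  ), class = "trna_pool")
}

#' @export
print.trna_pool <- function(x, ...) {
  cat("tRNA pool: ", x$trnaome_size, " genes over ",
      x$anticodon_type_count, " anticodon types (",
      nrow(x$removed), " records removed; code ", x$code_id, ")\n", sep = "")
  invisible(x)
}

#' Anticodon-repertoire diagnostics
#'
#' Reports the anticodon-type count against the theoretical minimum of 30
#' types needed to read all sense codons, and lists sense codons (and whole
#' amino acids) that no anticodon in the pool can decode under the wobble
#' rules.  This is the mechanism that surfaces a CGN-decoding gap: a pool
#' whose arginine repertoire is only the TCT anticodon covers AGA/AGG but
#' leaves all four CGN codons unreadable.
#'
#' @param pool a \code{trna_pool}
#' @param code a \code{genetic_code}
#' @param rules a \code{wobble_rules} object (default eukaryotic box rules)
#' @param min_types theoretical minimum anticodon-type count (default 30)
#' @return list with \code{anticodon_type_count}, \code{below_minimum},
#'   \code{uncovered_codons}, \code{uncovered_amino_acids}
#' @export
anticodon_diagnostics <- function(pool, code, rules = wobble_rules(),
                                  min_types = 30L) {
  W <- codon_absolute_adaptiveness(pool, rules, code)
  uncovered <- names(W)[W == 0]
  aa_all <- split(code$sense_codons, code$codon_to_aa[code$sense_codons])
  uncovered_aa <- names(aa_all)[vapply(aa_all, function(cods)
    all(cods %in% uncovered), logical(1))]
  list(
    anticodon_type_count = pool$anticodon_type_count,
    below_minimum = pool$anticodon_type_count < min_types,
    uncovered_codons = uncovered,
    uncovered_amino_acids = uncovered_aa
  )
}

#' Write a tRNA pool's gene-copy table to TSV
#' @param pool a \code{trna_pool}
#' @param path output file
#' @param code a \code{genetic_code} for annotation columns
#' @return invisibly, the data.frame written
#' @export
write_tgcn <- function(pool, path, code = get_code(pool$code_id)) {
  ac <- names(pool$tgcn)
  df <- data.frame(anticodon = ac,
                   implied_codon = anticodon_to_codon(ac),
                   amino_acid = code$codon_to_aa[anticodon_to_codon(ac)],
                   copies = as.integer(pool$tgcn),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
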