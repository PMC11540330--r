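#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

#' All 64 DNA codons in alphabetical order
#' @return character vector of length 64
#' @export
all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))[
    order(as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0)))]
}

STOP_TOKEN <- "*"

.code_cache <- new.env(parent = emptyenv())

#' Load a nuclear genetic code
#'
#' Codes are read from plain-text tables (codon TAB amino acid) shipped with
#' the package, so additional codes can be added without code changes.  The
#' \code{ctg_ser} and \code{ctg_ala} codes carry the budding-yeast CTG
#' reassignment (CTG read as serine in the Serinales/Ascoideales sense, or
#' alanine in the Alaninales sense); they differ from the standard nuclear
#' code only at codon CTG.
#'
#' @param code_id one of \code{"standard"}, \code{"ctg_ser"}, \code{"ctg_ala"},
#'   or the id of any additional table placed in
#'   \code{inst/extdata/genetic_codes/}.
#' @return an object of class \code{genetic_code} with components
#'   \code{code_id}, \code{codon_to_aa} (named character over all 64 codons,
#'   stops marked \code{"*"}), \code{stop_codons}, \code{sense_codons},
#'   \code{degeneracy} (named integer, amino acid to number of synonymous
#'   codons), and \code{degenerate_codons} (sense codons whose amino acid has
#'   two or more synonymous codons).
#' @examples
#' code <- get_code("standard")
#' code$codon_to_aa[["CTG"]]        # "Leu"
#' get_code("ctg_ser")$codon_to_aa[["CTG"]]  # "Ser"
#' @export
get_code <- function(code_id) {
  stopifnot(is.character(code_id), length(code_id) == 1L)
  if (!is.null(.code_cache[[code_id]])) return(.code_cache[[code_id]])
  dir <- system.file("extdata", "genetic_codes", package = "cubevol")
  path <- file.path(dir, paste0(code_id, ".tsv"))
  if (!file.exists(path)) {
    avail <- sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$"))
    stop("unknown code_id '", code_id, "'; available: ",
         paste(avail, collapse = ", "))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("codon", "aa"),
                           stringsAsFactors = FALSE, comment.char = "")
  codon_to_aa <- stats::setNames(tab$aa, tab$codon)
  if (length(codon_to_aa) != 64L || !setequal(names(codon_to_aa), all_codons()))
    stop("code table '", code_id, "' must cover exactly the 64 DNA codons")
  codon_to_aa <- codon_to_aa[all_codons()]
  stop_codons <- names(codon_to_aa)[codon_to_aa == STOP_TOKEN]
  sense_codons <- setdiff(names(codon_to_aa), stop_codons)
  degeneracy <- table(codon_to_aa[sense_codons])
  degeneracy <- stats::setNames(as.integer(degeneracy), names(degeneracy))
  degenerate_codons <- sense_codons[
    degeneracy[codon_to_aa[sense_codons]] >= 2L]
  code <- structure(list(
    code_id = code_id,
    codon_to_aa = codon_to_aa,
    stop_codons = stop_codons,
    sense_codons = sense_codons,
    degeneracy = degeneracy,
    degenerate_codons = degenerate_codons
  ), class = "genetic_code")
  .code_cache[[code_id]] <- code
  code
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code '", x$code_id, "': ", length(x$sense_codons),
      " sense codons, ", length(x$stop_codons), " stops, ",
      length(x$degenerate_codons), " degenerate codons\n", sep = "")
  invisible(x)
}

#' Synonymous codons of an amino acid
#' @param aa three-letter amino-acid label
#' @param code a \code{genetic_code}
#' @return character vector of codons
#' @export
codons_for_aa <- function(aa, code) {
  names(code$codon_to_aa)[code$codon_to_aa == aa]
}

.split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not divisible by 3")
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Translates frame-0 codons under the given code.  A terminal stop codon is
#' dropped; an internal stop is an error unless \code{internal_stop = "mask"},
#' in which case it is emitted as \code{"*"}.  Codons containing characters
#' outside ACGT are an error under the default strict policy, or emitted as
#' \code{"X"} under \code{ambiguous = "mask"}.
#'
#' @param cds DNA string (T convention), length divisible by 3
#' @param code a \code{genetic_code}
#' @param internal_stop \code{"error"} or \code{"mask"}
#' @param ambiguous \code{"error"} or \code{"mask"}
#' @param collapse if TRUE (default) return a single one-letter-code string;
#'   otherwise a character vector of three-letter residue labels
#' @return translated protein, form controlled by \code{collapse}
#' @export
translate_cds <- function(cds, code, internal_stop = c("error", "mask"),
                          ambiguous = c("error", "mask"), collapse = TRUE) {
  internal_stop <- match.arg(internal_stop)
  ambiguous <- match.arg(ambiguous)
  cds <- toupper(cds)
  codons <- .split_codons(cds)
  if (length(codons) == 0L) return(if (collapse) "" else character(0))
  known <- codons %in% all_codons()
  if (any(!known)) {
    if (ambiguous == "error")
      stop("ambiguous codon(s) at position(s) ",
           paste(which(!known), collapse = ", "))
  }
  aa <- rep("X", length(codons))
  aa[known] <- code$codon_to_aa[codons[known]]
  # terminal stop dropped
  if (length(aa) > 0L && aa[length(aa)] == STOP_TOKEN)
    aa <- aa[-length(aa)]
  if (any(aa == STOP_TOKEN) && internal_stop == "error")
    stop("internal stop codon at codon position(s) ",
         paste(which(aa == STOP_TOKEN), collapse = ", "))
  if (!collapse) return(aa)
  paste(AA_ONE[ifelse(aa %in% names(AA_ONE), aa, "X")], collapse = "")
}

AA_ONE <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
            Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
            Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
            Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
            "*" = "*", X = "X")
AA_THREE <- stats::setNames(names(AA_ONE), AA_ONE)

#' Census of degeneracy classes
#'
#' Counts how many amino acids fall in each synonymous-family size under a
#' code (level 1 = nondegenerate).  Under the standard nuclear code this is
#' \{1: 2, 2: 9, 3: 1, 4: 5, 6: 3\}.
#'
#' @param code a \code{genetic_code}
#' @return named integer vector, degeneracy level to amino-acid count
#' @export
degeneracy_class_census <- function(code) {
  tab <- table(code$degeneracy)
  stats::setNames(as.integer(tab), names(tab))
}

#' Number of unordered codon pairs
#'
#' Distinct unordered pairs among \code{n} codons, \code{n * (n - 1) / 2};
#' with the 61 sense codons of the standard code this is the 1,830 pairwise
#' RSCU combinations of a full codon-codon correlation screen.
#'
#' @param code a \code{genetic_code}, or an integer codon count
#' @return integer
#' @export
codon_pair_count <- function(code) {
  n <- if (inherits(code, "genetic_code")) length(code$sense_codons)
       else as.integer(code)
  as.integer(n * (n - 1L) / 2L)
}

#' Reverse complement of a DNA string
#' @param x DNA string(s)
#' @return reverse complement, same convention
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Codon decoded by Watson-Crick pairing of an anticodon
#'
#' Anticodons are stored in the DNA convention; the Watson-Crick codon is the
#' reverse complement (anticodon TCT reads codon AGA).
#' @param anticodon 3-mer(s) over ACGT
#' @return codon 3-mer(s)
#' @export
anticodon_to_codon <- function(anticodon) revcomp(anticodon)
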