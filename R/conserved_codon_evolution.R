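GAP_CODON <- "---"

.split_aln_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("gapped codon string length not divisible by 3")
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces every aligned residue by its source codon and every protein gap
#' by the gap codon \code{"---"}, validating that each ungapped coding
#' sequence translates to its ungapped protein row (a terminal stop codon on
#' the CDS is tolerated and dropped).
#'
#' @param protein_alignment named character vector of equal-length gapped
#'   protein rows (one-letter codes, gap \code{"-"})
#' @param cds_by_label named character vector of unaligned coding sequences,
#'   names matching the alignment rows
#' @param code a \code{genetic_code}
#' @return object of class \code{codon_alignment}: list with \code{rows}
#'   (named character, gapped codon strings), \code{n_columns} (in codons),
#'   \code{code_id}
#' @export
back_translate_alignment <- function(protein_alignment, cds_by_label, code) {
  labs <- names(protein_alignment)
  stopifnot(!is.null(labs), all(labs %in% names(cds_by_label)))
  widths <- unique(nchar(protein_alignment))
  if (length(widths) != 1L) stop("protein alignment rows differ in length")
  rows <- stats::setNames(character(length(labs)), labs)
  for (lab in labs) {
    prot_row <- strsplit(protein_alignment[[lab]], "")[[1]]
    cds <- toupper(cds_by_label[[lab]])
    codons <- .split_codons(cds)
    if (length(codons) > 0L &&
        code$codon_to_aa[codons[length(codons)]] %in% STOP_TOKEN)
      codons <- codons[-length(codons)]
    translated <- AA_ONE[code$codon_to_aa[codons]]
    residues <- prot_row[prot_row != "-"]
    if (length(translated) != length(residues))
      stop("label '", lab, "': CDS encodes ", length(translated),
           " residues but alignment row has ", length(residues))
    mism <- which(translated != residues)
    if (length(mism) > 0L)
      stop("label '", lab, "': translation mismatch at ungapped residue ",
           mism[1L], " (", translated[mism[1L]], " vs ", residues[mism[1L]], ")")
    out <- character(length(prot_row))
    out[prot_row == "-"] <- GAP_CODON
    out[prot_row != "-"] <- codons
    rows[[lab]] <- paste(out, collapse = "")
  }
  structure(list(rows = rows, n_columns = widths, code_id = code$code_id),
            class = "codon_alignment")
}

#' Columns where a residue is conserved
#'
#' Returns alignment columns where the focal residue's fraction reaches the
#' threshold.  By default the fraction is taken over non-gap entries (gaps
#' neither support nor count against conservation); \code{denominator =
#' "all"} divides by the full number of rows instead, for sensitivity
#' analysis.  All-gap columns are never returned.
#'
#' @param protein_alignment named character vector of gapped protein rows
#' @param residue one-letter residue code (e.g. \code{"R"})
#' @param threshold conservation fraction in (0, 1], e.g. 0.8 or 0.6
#' @param denominator \code{"nongap"} (default) or \code{"all"}
#' @return integer vector of 1-based column indices
#' @export
conserved_residue_sites <- function(protein_alignment, residue,
                                    threshold = 0.8,
                                    denominator = c("nongap", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(threshold > 0, threshold <= 1, nchar(residue) == 1L)
  mat <- do.call(rbind, strsplit(unname(protein_alignment), ""))
  hits <- colSums(mat == residue)
  nongap <- colSums(mat != "-")
  denom <- if (denominator == "nongap") nongap else rep(nrow(mat), ncol(mat))
  frac <- ifelse(denom > 0, hits / denom, 0)
  which(frac >= threshold & nongap > 0)
}

#' Consensus codon of a group at an alignment column
#'
#' The codon reaching the threshold fraction of the group's non-gap entries,
#' or \code{NA} when none does.  At thresholds above 0.5 ties are impossible;
#' at exactly 0.5 an exact tie yields \code{NA}.
#'
#' @param codon_alignment a \code{codon_alignment}
#' @param column 1-based codon column
#' @param members row labels forming the group
#' @param threshold fraction in (0, 1]
#' @return codon string or \code{NA_character_}
#' @export
group_codon_consensus <- function(codon_alignment, column, members,
                                  threshold = 0.8) {
  stopifnot(all(members %in% names(codon_alignment$rows)))
  start <- (column - 1L) * 3L + 1L
  codons <- vapply(codon_alignment$rows[members], substr, character(1),
                   start, start + 2L)
  codons <- codons[codons != GAP_CODON]
  if (length(codons) == 0L) return(NA_character_)
  tab <- sort(table(codons), decreasing = TRUE)
  frac <- tab[1L] / length(codons)
  if (frac > threshold || (frac == threshold &&
                           sum(tab == tab[1L]) == 1L))
    return(names(tab)[1L])
  NA_character_
}

#' Most parsimonious ancestral codon on a 3-group rooted topology
#'
#' Fitch parsimony on ((A, B), O): the ingroup node state is the
#' intersection of the two ingroup codons if nonempty, else their union; the
#' root state is the intersection with the outgroup if nonempty, otherwise
#' the ambiguity is resolved toward the outgroup state (flagged, so
#' summaries can be recomputed with and without resolved sites).  Branch
#' transitions are reported as ancestral-to-descendant codon pairs wherever
#' the inferred ancestor differs from a group consensus.
#'
#' @param ingroup_a,ingroup_b,outgroup consensus codons (no NA)
#' @return list with \code{ancestral}, \code{outgroup_resolved} (logical),
#'   \code{transitions} (data.frame branch / from / to)
#' @export
ancestral_codon_fitch <- function(ingroup_a, ingroup_b, outgroup) {
  stopifnot(!is.na(ingroup_a), !is.na(ingroup_b), !is.na(outgroup))
  inter_in <- intersect(ingroup_a, ingroup_b)
  ingroup_set <- if (length(inter_in) > 0) inter_in
                 else union(ingroup_a, ingroup_b)
  root_set <- intersect(ingroup_set, outgroup)
  outgroup_resolved <- FALSE
  if (length(root_set) > 0) {
    ancestral <- root_set[1L]
  } else {
    ancestral <- outgroup
    outgroup_resolved <- TRUE
  }
  # ingroup-node assignment minimizing changes given the root
  ingroup_state <- if (ancestral %in% ingroup_set) ancestral
                   else ingroup_set[1L]
  trans <- data.frame(branch = character(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE)
  add <- function(branch, from, to) {
    if (from != to)
      trans <<- rbind(trans, data.frame(branch = branch, from = from,
                                        to = to, stringsAsFactors = FALSE))
  }
  add("ingroup_stem", ancestral, ingroup_state)
  add("A", ingroup_state, ingroup_a)
  add("B", ingroup_state, ingroup_b)
  add("outgroup", ancestral, outgroup)
  list(ancestral = ancestral, outgroup_resolved = outgroup_resolved,
       transitions = trans)
}

#' Conserved-site report for one ortholog family
#'
#' Finds residue-conserved columns, takes per-group codon consensus at each,
#' and infers the parsimonious ancestral codon with branch transitions for
#' the sites where all three groups have a consensus.
#'
#' @param protein_alignment named gapped protein rows
#' @param codon_alignment matching \code{codon_alignment}
#' @param groups named character: row label to group id
#' @param topology character of length 3: the two ingroup group ids then the
#'   outgroup id
#' @param residue focal residue (default \code{"R"}, arginine)
#' @param global_threshold residue-conservation threshold across all rows
#' @param group_threshold codon-consensus threshold within groups
#' @param ortholog_id label carried into the report
#' @return data.frame with one row per conserved site: \code{ortholog_id},
#'   \code{column}, \code{global_fraction}, per-group consensus columns,
#'   \code{ancestral} (codon or NA for sites lacking full consensus),
#'   \code{outgroup_resolved}, and one \code{to_<group>} transition label per
#'   ingroup branch
#' @export
conserved_site_report <- function(protein_alignment, codon_alignment, groups,
                                  topology, residue = "R",
                                  global_threshold = 0.8,
                                  group_threshold = 0.8,
                                  ortholog_id = NA_character_) {
  stopifnot(length(topology) == 3L, all(topology %in% groups))
  cols <- conserved_residue_sites(protein_alignment, residue,
                                  global_threshold)
  if (length(cols) == 0L) return(.empty_site_report(topology))
  mat <- do.call(rbind, strsplit(unname(protein_alignment), ""))
  rows <- lapply(cols, function(col) {
    nongap <- sum(mat[, col] != "-")
    gfrac <- sum(mat[, col] == residue) / nongap
    cons <- vapply(topology, function(g) {
      group_codon_consensus(codon_alignment, col,
                            names(groups)[groups == g], group_threshold)
    }, character(1))
    anc <- NA_character_
    resolved <- NA
    branch_codon <- stats::setNames(rep(NA_character_, 2L), topology[1:2])
    if (!anyNA(cons)) {
      fit <- ancestral_codon_fitch(cons[[1L]], cons[[2L]], cons[[3L]])
      anc <- fit$ancestral
      resolved <- fit$outgroup_resolved
      branch_codon <- stats::setNames(cons[1:2], topology[1:2])
    }
    out <- data.frame(ortholog_id = ortholog_id, column = col,
                      global_fraction = gfrac, stringsAsFactors = FALSE)
    for (g in topology) out[[paste0("consensus_", g)]] <- cons[[g]]
    out$ancestral <- anc
    out$outgroup_resolved <- resolved
    for (g in topology[1:2]) out[[paste0("to_", g)]] <- branch_codon[[g]]
    out
  })
  do.call(rbind, rows)
}

.empty_site_report <- function(topology) {
  out <- data.frame(ortholog_id = character(0), column = integer(0),
                    global_fraction = numeric(0), stringsAsFactors = FALSE)
  for (g in topology) out[[paste0("consensus_", g)]] <- character(0)
  out$ancestral <- character(0)
  out$outgroup_resolved <- logical(0)
  for (g in topology[1:2]) out[[paste0("to_", g)]] <- character(0)
  out
}

#' Ancestral-to-descendant codon transition table
#'
#' Tabulates, over the conserved sites of a report, how often each ancestral
#' codon was retained or replaced along the ingroup branches.  Sites without
#' a full per-group consensus (ancestral NA) are tallied separately as
#' ambiguous.
#'
#' @param report data.frame from \code{\link{conserved_site_report}} (rows
#'   from several orthologs may be concatenated)
#' @param branches names of the \code{to_<group>} columns to tabulate
#'   (default: all columns starting with \code{"to_"})
#' @return list with \code{matrix} (ancestral x descendant counts),
#'   \code{retained} (named count where descendant equals ancestor, the
#'   matrix diagonal), \code{n_ambiguous}, \code{n_sites}
#' @export
transition_table <- function(report, branches = NULL) {
  if (is.null(branches))
    branches <- grep("^to_", names(report), value = TRUE)
  usable <- report[!is.na(report$ancestral), , drop = FALSE]
  anc <- rep(usable$ancestral, times = length(branches))
  des <- unlist(lapply(branches, function(b) usable[[b]]), use.names = FALSE)
  lev <- sort(unique(c(anc, des)))
  mat <- table(factor(anc, levels = lev), factor(des, levels = lev))
  mat <- unclass(mat)
  names(dimnames(mat)) <- c("ancestral", "descendant")
  list(matrix = mat,
       retained = stats::setNames(diag(mat), lev),
       n_ambiguous = sum(is.na(report$ancestral)),
       n_sites = nrow(report))
}

#' Hamming distance between two codons
#'
#' Number of base substitutions separating two codons (0-3).  Of the eight
#' ordered CGN-to-AGN arginine codon pairs, six require two substitutions
#' and two (CGA-AGA, CGG-AGG) require one.
#'
#' @param c1,c2 codon strings over ACGT
#' @return integer in 0..3
#' @export
mutation_distance <- function(c1, c2) {
  c1 <- toupper(c1); c2 <- toupper(c2)
  if (!(c1 %in% all_codons()) || !(c2 %in% all_codons()))
    stop("invalid codon: ", c1, " / ", c2)
  sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
}
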