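#' Per-genome codon-usage profile
#'
#' Composes the full genomic pipeline for a set of genomes: read the CDS
#' FASTA, count codons under the genome's code, compute gene-level RSCU and
#' GC/Nc statistics, parse and filter the tRNAscan-SE output into a
#' gene-copy pool, build the adaptiveness table, compute per-gene tAI and
#' the genome S-value, and run the anticodon diagnostics.  Failures are
#' isolated per genome: a genome whose inputs are malformed contributes a
#' row to the failure log while the run continues.
#'
#' @param genomes list of lists, each with \code{id}, \code{cds_path},
#'   \code{trnascan_path}, and optionally \code{code_id} (default
#'   "standard")
#' @param rules a \code{wobble_rules} set
#' @param rscu_method genome-average mode, \code{"mean"} or \code{"pooled"}
#' @param out_dir optional directory for per-gene TSVs
#' @return list with \code{summary} (data.frame, one row per successful
#'   genome: id, n_genes, mean gc/gc3/gc3s, mean nc, trnaome_size,
#'   anticodon_types, below_minimum, n_uncovered_codons, s_value),
#'   \code{rscu_matrix} (genomes x degenerate codons), \code{per_genome}
#'   (detailed objects), and \code{failures} (id + condition message)
#' @export
run_genome_profile <- function(genomes, rules = wobble_rules(),
                               rscu_method = c("mean", "pooled"),
                               out_dir = NULL) {
  rscu_method <- match.arg(rscu_method)
  summaries <- list()
  rscu_rows <- list()
  detail <- list()
  failures <- data.frame(id = character(0), message = character(0),
                         stringsAsFactors = FALSE)
  for (gn in genomes) {
    res <- tryCatch({
      code <- get_code(if (is.null(gn$code_id)) "standard" else gn$code_id)
      counts <- read_cds_counts(gn$cds_path, code)
      if (length(counts) == 0L) stop("no coding sequences parsed")
      profiles <- lapply(counts, rscu, code = code)
      genome_rscu <- if (rscu_method == "mean")
        genome_average_rscu(profiles) else
        genome_average_rscu(counts, method = "pooled")
      records <- parse_trnascan(gn$trnascan_path)
      pool <- filter_trnas(records, code)
      diag <- anticodon_diagnostics(pool, code, rules)
      adapt <- build_adaptiveness(pool, rules, code)
      stats_df <- genome_selection_stats(counts, adapt, code)
      sel <- s_value(stats_df)
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(stats_df,
                           file.path(out_dir, paste0(gn$id, "_genes.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      list(code = code, genome_rscu = genome_rscu, pool = pool,
           diagnostics = diag, adapt = adapt, gene_stats = stats_df,
           selection = sel)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures, data.frame(
        id = gn$id, message = conditionMessage(res),
        stringsAsFactors = FALSE))
      next
    }
    summaries[[gn$id]] <- data.frame(
      id = gn$id,
      n_genes = nrow(res$gene_stats),
      mean_gc = mean(res$gene_stats$gc, na.rm = TRUE),
      mean_gc3 = mean(res$gene_stats$gc3, na.rm = TRUE),
      mean_gc3s = mean(res$gene_stats$gc3s, na.rm = TRUE),
      mean_nc = mean(res$gene_stats$nc, na.rm = TRUE),
      trnaome_size = res$pool$trnaome_size,
      anticodon_types = res$pool$anticodon_type_count,
      below_minimum = res$diagnostics$below_minimum,
      n_uncovered_codons = length(res$diagnostics$uncovered_codons),
      s_value = res$selection$s_value,
      stringsAsFactors = FALSE)
    rscu_rows[[gn$id]] <- res$genome_rscu$values
    detail[[gn$id]] <- res
  }
  rscu_matrix <- if (length(rscu_rows) > 0) do.call(rbind, rscu_rows)
                 else NULL
  summary_df <- if (length(summaries) > 0) do.call(rbind, summaries)
                else NULL
  if (!is.null(summary_df)) rownames(summary_df) <- NULL
  if (!is.null(out_dir) && !is.null(summary_df)) {
    utils::write.table(summary_df, file.path(out_dir, "genome_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(id = rownames(rscu_matrix), rscu_matrix,
                                  check.names = FALSE),
                       file.path(out_dir, "rscu_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(summary = summary_df, rscu_matrix = rscu_matrix,
       per_genome = detail, failures = failures)
}

#' Conserved-residue pipeline over ortholog families
#'
#' Validates and back-translates each family, builds the per-site report at
#' the requested thresholds, and tabulates codon transitions over the
#' ingroup branches.
#'
#' @param families list of lists with \code{ortholog_id},
#'   \code{protein_alignment} (named gapped rows) and \code{cds} (named,
#'   unaligned)
#' @param groups named character, taxon label to group id
#' @param topology the two ingroup ids then the outgroup id
#' @param residue focal residue, default arginine
#' @param global_threshold,group_threshold conservation thresholds
#' @param code a \code{genetic_code}
#' @return list with \code{report} (concatenated site report),
#'   \code{transitions} (from \code{\link{transition_table}}),
#'   \code{n_sites}, \code{ancestral_census} (table of inferred ancestors)
#' @export
run_conserved_residue <- function(families, groups, topology,
                                  residue = "R", global_threshold = 0.8,
                                  group_threshold = 0.8,
                                  code = get_code("standard")) {
  if (length(families) == 0L) stop("no ortholog families supplied")
  reports <- lapply(families, function(fam) {
    aln <- back_translate_alignment(fam$protein_alignment, fam$cds, code)
    conserved_site_report(fam$protein_alignment, aln, groups, topology,
                          residue = residue,
                          global_threshold = global_threshold,
                          group_threshold = group_threshold,
                          ortholog_id = fam$ortholog_id)
  })
  report <- do.call(rbind, reports)
  list(report = report,
       transitions = transition_table(report),
       n_sites = nrow(report),
       ancestral_census = table(report$ancestral, useNA = "ifany"))
}
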