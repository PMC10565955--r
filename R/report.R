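# Cross-genome comparison table: one column per genome, rows matching the
# standard draft-genome statistics table (lengths in Mb/kb, 3 decimals).
# Formatting happens here and only here; all upstream values are plain bp.

#' Build a cross-genome comparison table
#'
#' Assembles per-genome assembly and annotation summaries into the standard
#' side-by-side comparison: length, N content, contig counts and sizes,
#' N50, gene-model counts, genes per contig and exons per gene.
#'
#' @param summaries Named list, one element per genome, each a list with
#'   `assembly` (an `"assembly_summary"`) and optionally `annotation` (an
#'   `"annotation_summary"`).
#' @param digits Decimals for Mb/kb and mean values (default 3).
#' @return data.frame with a `parameter` column and one column per genome;
#'   `NA` for annotation rows when no annotation summary was given.
#' @export
comparison_table <- function(summaries, digits = 3) {
  stopifnot(length(summaries) >= 1)
  if (is.null(names(summaries)) || any(!nzchar(names(summaries)))) {
    stop("summaries must be a named list (one name per genome)")
  }
  params <- c("Length (Mb)", "N's (count)", "N's (%)", "Number of contigs",
              "Longest contig (Kb)", "Average contig length (Kb)",
              "N50 (Kb)", "Number of gene models",
              "Max. number of genes per contig",
              "Average number of genes per contig",
              "Max. number of exons per gene",
              "Average number of exons per gene")
  cols <- lapply(summaries, function(s) {
    a <- s$assembly
    stopifnot(inherits(a, "assembly_summary"))
    ann <- s$annotation
    ann_vals <- if (is.null(ann)) rep(NA_real_, 5) else c(
      ann$n_genes, ann$genes_per_contig$max,
      round(ann$genes_per_contig$mean, digits),
      ann$exons_per_gene$max, round(ann$exons_per_gene$mean, digits))
    c(round(a$total_length / 1e6, digits), a$n_count,
      round(a$n_percent, digits), a$n_contigs,
      round(a$longest / 1e3, digits), round(a$mean_length / 1e3, digits),
      round(a$n50 / 1e3, digits), ann_vals)
  })
  out <- data.frame(parameter = params, stringsAsFactors = FALSE)
  for (nm in names(summaries)) out[[nm]] <- cols[[nm]]
  out
}
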