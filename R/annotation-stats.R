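# Gene-architecture distributions from an annotation set: genes per contig,
# exons per gene, intron lengths. All per-gene quantities are taken on the
# representative transcript (largest summed CDS, ties by smallest id);
# exon-feature coordinates are used, not CDS gaps.

#' Genes per contig
#'
#' The denominator of the mean is the TOTAL number of contigs in the
#' universe, including contigs that carry no gene; those appear with count
#' 0. This matches the convention of cross-genome annotation tables where
#' the mean is gene models divided by all contigs of the (decontaminated)
#' assembly.
#'
#' @param annotation An [annotation_set()].
#' @param universe An [assembly()] or a character vector of contig ids; every
#'   gene's contig must belong to it.
#' @return List with `counts` (named integer vector over the whole
#'   universe), `mean` and `max`.
#' @export
genes_per_contig <- function(annotation, universe) {
  stopifnot(inherits(annotation, "annotation_set"))
  if (inherits(universe, "assembly")) universe <- contig_ids(universe)
  universe <- as.character(universe)
  if (length(universe) == 0) stop("empty contig universe")
  off <- setdiff(annotation$genes$contig_id, universe)
  if (length(off) > 0) {
    stop("gene(s) on contig(s) absent from the universe: ",
         paste(off, collapse = ", "))
  }
  counts <- stats::setNames(rep(0L, length(universe)), universe)
  tab <- table(annotation$genes$contig_id)
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, mean = sum(counts) / length(counts),
       max = if (length(counts) > 0) max(counts) else 0L)
}

#' Exons per gene
#'
#' Counts exons of each gene's representative transcript. An optional
#' outlier threshold excludes genes with more exons than the threshold from
#' the mean and max (they remain in `counts` for plotting) and reports them
#' in `excluded_genes`; this mirrors the occasional manual removal of an
#' annotation artefact with an absurd exon count.
#'
#' @param annotation An [annotation_set()].
#' @param outlier_threshold Optional numeric; genes with exon count
#'   strictly greater are excluded from `mean`/`max`. Default `NULL` (no
#'   exclusion).
#' @return List with `counts` (named by gene id, raw), `mean`, `max`
#'   (over non-excluded genes) and `excluded_genes`.
#' @export
exons_per_gene <- function(annotation, outlier_threshold = NULL) {
  stopifnot(inherits(annotation, "annotation_set"))
  rex <- representative_exons(annotation)
  counts <- stats::setNames(rep(0L, nrow(annotation$genes)),
                            annotation$genes$gene_id)
  tab <- table(rex$gene_id)
  counts[names(tab)] <- as.integer(tab)
  excluded <- character()
  keep <- counts
  if (!is.null(outlier_threshold)) {
    excluded <- names(counts)[counts > outlier_threshold]
    keep <- counts[!names(counts) %in% excluded]
  }
  list(counts = counts,
       mean = if (length(keep) > 0) mean(keep) else NA_real_,
       max = if (length(keep) > 0) max(keep) else NA_integer_,
       excluded_genes = excluded)
}

#' Intron lengths
#'
#' For consecutive exons (s1..e1), (s2..e2) of a representative transcript
#' the intron length is `s2 - e1 - 1` bp. Single-exon transcripts contribute
#' nothing. Transcripts with overlapping exons are skipped and flagged;
#' non-positive gaps between sorted non-overlapping exons (abutting exons)
#' are reported as annotation errors and excluded from the lengths.
#'
#' @param annotation An [annotation_set()].
#' @return List with `lengths` (integer vector of intron lengths in bp),
#'   `flagged_transcripts` (overlapping exons) and `n_nonpositive` (gaps
#'   <= 0 encountered and dropped).
#' @export
intron_lengths <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  rex <- representative_exons(annotation)
  lengths <- integer()
  flagged <- character()
  n_nonpos <- 0L
  by_tx <- split(rex[, c("start", "end")], rex$transcript_id)
  for (tx in names(by_tx)) {
    e <- by_tx[[tx]]
    if (nrow(e) < 2) next
    # exons arrive sorted by start; overlap = next start <= previous end
    if (any(e$start[-1] <= e$end[-nrow(e)])) {
      flagged <- c(flagged, tx)
      next
    }
    gaps <- e$start[-1] - e$end[-nrow(e)] - 1L
    n_nonpos <- n_nonpos + sum(gaps <= 0)
    lengths <- c(lengths, gaps[gaps > 0])
  }
  if (length(flagged) > 0) {
    warning("transcript(s) with overlapping exons skipped: ",
            paste(flagged, collapse = ", "))
  }
  list(lengths = lengths, flagged_transcripts = flagged,
       n_nonpositive = n_nonpos)
}

#' Annotation architecture summary
#'
#' Convenience wrapper bundling [genes_per_contig()], [exons_per_gene()] and
#' [intron_lengths()] for one genome.
#'
#' @inheritParams genes_per_contig
#' @inheritParams exons_per_gene
#' @return List of class `"annotation_summary"` with `n_genes`,
#'   `genes_per_contig`, `exons_per_gene`, `intron_lengths` and
#'   `excluded_genes`.
#' @export
summarize_annotation <- function(annotation, universe,
                                 outlier_threshold = NULL) {
  gpc <- genes_per_contig(annotation, universe)
  epg <- exons_per_gene(annotation, outlier_threshold)
  il <- intron_lengths(annotation)
  structure(list(n_genes = nrow(annotation$genes), genes_per_contig = gpc,
                 exons_per_gene = epg, intron_lengths = il,
                 excluded_genes = epg$excluded_genes),
            class = "annotation_summary")
}
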