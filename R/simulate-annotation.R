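# Seeded synthetic gene-model generator.
#
# Genes are placed left to right on host contigs: per contig a Poisson
# number of genes, per gene an exon count drawn from a shifted Poisson (the
# clade-level knob behind "exons per gene" comparisons), exon lengths
# multiples of 3 so the CDS translates cleanly, intron lengths log-uniform.
# The CDS equals the exon chain, so protein length = total exon length / 3.
# A gene that cannot fit on its contig is re-drawn a bounded number of
# times, then dropped from that contig's quota (never silently truncated).

#' Simulate gene models on a synthetic assembly
#'
#' @param sim A `"sim_assembly"` from [simulate_assembly()] (genes are
#'   placed on host contigs only; contaminants stay gene-less, as they
#'   would after decontamination).
#' @param genes_per_contig_mean Poisson mean of genes per host contig
#'   (default 2.4, the genes-per-contig load of a long-read acoelomorph
#'   draft genome).
#' @param exon_count_mean Mean exons per gene; exon count is
#'   `1 + rpois(exon_count_mean - 1)` (default 3.3).
#' @param exon_length_range Exon length range in bp; drawn uniformly then
#'   rounded up to a multiple of 3.
#' @param intron_length_range Intron length range in bp, drawn log-uniformly
#'   (introns are the heavy-tailed part of gene architecture).
#' @param max_retries Re-draws allowed before a gene is dropped.
#' @param seed Integer seed.
#' @return List of class `"sim_annotation"`: `annotation` (an
#'   [annotation_set()] whose universe is the full assembly), `proteins`
#'   (named character, one per transcript, translated from the CDS with the
#'   standard code), `gff3` (character vector of GFF3 lines) and `manifest`
#'   (data.frame per gene: `gene_id`, `contig_id`, `n_exons`,
#'   `mean_exon_length`, `total_exon_bp`, `protein_length`, plus
#'   `intron_lengths` as a list column).
#' @export
simulate_annotation <- function(sim, genes_per_contig_mean = 2.4,
                                exon_count_mean = 3.3,
                                exon_length_range = c(60L, 300L),
                                intron_length_range = c(6L, 5000L),
                                max_retries = 50L, seed = 1) {
  stopifnot(inherits(sim, "sim_assembly"))
  set.seed(seed)
  man <- sim$manifest
  host <- man[!man$is_contaminant, , drop = FALSE]

  draw_gene <- function(contig_len, offset) {
    for (try in seq_len(max_retries)) {
      n_ex <- 1L + stats::rpois(1, max(0, exon_count_mean - 1))
      ex_len <- sample(exon_length_range[1]:exon_length_range[2], n_ex,
                       replace = TRUE)
      ex_len <- as.integer(3L * ceiling(ex_len / 3))
      introns <- if (n_ex > 1) {
        lr <- log(intron_length_range)
        as.integer(round(exp(stats::runif(n_ex - 1, lr[1], lr[2]))))
      } else integer()
      span <- sum(ex_len) + sum(introns)
      if (offset + span - 1L <= contig_len) {
        return(list(ex_len = ex_len, introns = introns, span = span))
      }
    }
    NULL
  }

  genes <- list(); transcripts <- list(); exons <- list()
  manifest <- list(); proteins <- character()
  gid <- 0L
  for (i in seq_len(nrow(host))) {
    n_genes <- stats::rpois(1, genes_per_contig_mean)
    pos <- 1L
    for (k in seq_len(n_genes)) {
      # small random intergenic spacer
      pos <- pos + sample(10:200, 1)
      g <- draw_gene(host$length[i], pos)
      if (is.null(g)) next
      gid <- gid + 1L
      gene_id <- sprintf("gene_%05d", gid)
      tx_id <- paste0(gene_id, ".t1")
      starts <- pos + cumsum(c(0L, g$ex_len[-length(g$ex_len)] + g$introns))
      ends <- starts + g$ex_len - 1L
      genes[[gid]] <- data.frame(gene_id = gene_id,
                                 contig_id = host$contig_id[i],
                                 strand = "+", stringsAsFactors = FALSE)
      transcripts[[gid]] <- data.frame(transcript_id = tx_id,
                                       gene_id = gene_id,
                                       stringsAsFactors = FALSE)
      exons[[gid]] <- data.frame(transcript_id = tx_id, start = starts,
                                 end = ends, stringsAsFactors = FALSE)
      cds_seq <- paste(vapply(seq_along(starts), function(e)
        toupper(as.character(Biostrings::subseq(
          sim$assembly$seqs[[host$contig_id[i]]], starts[e], ends[e]))),
        character(1)), collapse = "")
      prot <- as.character(Biostrings::translate(
        Biostrings::DNAString(gsub("[^ACGT]", "N", cds_seq)),
        if.fuzzy.codon = "X"))
      proteins[[tx_id]] <- prot
      manifest[[gid]] <- data.frame(
        gene_id = gene_id, contig_id = host$contig_id[i],
        n_exons = length(g$ex_len),
        mean_exon_length = mean(g$ex_len),
        total_exon_bp = sum(g$ex_len),
        protein_length = sum(g$ex_len) / 3L, stringsAsFactors = FALSE)
      manifest[[gid]]$intron_lengths <- list(g$introns)
      pos <- pos + g$span
    }
  }
  genes <- do.call(rbind, genes)
  transcripts <- do.call(rbind, transcripts)
  exon_df <- do.call(rbind, exons)
  manifest <- do.call(rbind, manifest)
  if (is.null(genes)) stop("no gene fitted on any contig; config infeasible")

  ann <- annotation_set(genes, transcripts, exon_df, cds = exon_df,
                        contig_universe = man$contig_id)
  structure(list(annotation = ann, proteins = proteins,
                 gff3 = .gff3_lines(ann), manifest = manifest),
            class = "sim_annotation")
}

# GFF3 serialization of a (single-isoform) annotation set; used to emit
# synthetic fixtures that exercise read_gff3().
.gff3_lines <- function(ann) {
  lines <- "##gff-version 3"
  ex_by_tx <- split(ann$exons, ann$exons$transcript_id)
  cds_by_tx <- split(ann$cds, ann$cds$transcript_id)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    txs <- ann$transcripts[ann$transcripts$gene_id == g$gene_id, ,
                           drop = FALSE]
    exs <- ann$exons[ann$exons$transcript_id %in% txs$transcript_id, ,
                     drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$contig_id, min(exs$start), max(exs$end), g$strand, g$gene_id))
    for (tx in txs$transcript_id) {
      e <- ex_by_tx[[tx]]
      lines <- c(lines, sprintf(
        "%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$contig_id, min(e$start), max(e$end), g$strand, tx, g$gene_id))
      lines <- c(lines, sprintf(
        "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        g$contig_id, e$start, e$end, g$strand, tx, seq_len(nrow(e)), tx))
      cd <- cds_by_tx[[tx]]
      if (!is.null(cd)) {
        lines <- c(lines, sprintf(
          "%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
          g$contig_id, cd$start, cd$end, g$strand, tx, tx))
      }
    }
  }
  lines
}
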