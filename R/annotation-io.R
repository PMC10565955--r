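# Gene-model container and GFF3 input.
#
# Coordinates are 1-based inclusive throughout, the GFF3 convention.
# A gene model is gene -> >=1 transcripts -> sorted exon (and optional CDS)
# intervals; per-gene metrics are computed on one representative transcript.

#' Construct an annotation set
#'
#' @param genes data.frame with columns `gene_id`, `contig_id`, `strand`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (1-based inclusive).
#' @param cds Optional data.frame like `exons` for coding intervals.
#' @param contig_universe Optional character vector of all contig ids in the
#'   paired assembly; when supplied every gene's `contig_id` must belong to
#'   it.
#' @param warnings Character vector of parse warnings carried along (used by
#'   [read_gff3()]).
#'
#' @details The representative transcript of each gene is the one with the
#' largest summed CDS length, ties broken by the lexicographically smallest
#' transcript id; transcripts without CDS count as CDS length 0. Exons are
#' stored sorted by start within each transcript.
#'
#' @return An object of class `"annotation_set"`.
#' @export
annotation_set <- function(genes, transcripts, exons, cds = NULL,
                           contig_universe = NULL, warnings = character()) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "contig_id") %in% names(genes)),
            all(c("transcript_id", "gene_id") %in% names(transcripts)),
            all(c("transcript_id", "start", "end") %in% names(exons)))
  if (is.null(genes$strand)) genes$strand <- "+"

  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0) stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  orphan_tx <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(orphan_tx) > 0) {
    stop("transcript(s) reference unknown gene(s): ",
         paste(orphan_tx, collapse = ", "))
  }
  orphan_ex <- setdiff(exons$transcript_id, transcripts$transcript_id)
  if (length(orphan_ex) > 0) {
    stop("exon(s) reference unknown transcript(s): ",
         paste(orphan_ex, collapse = ", "))
  }
  if (nrow(exons) > 0 && any(exons$end < exons$start | exons$start < 1)) {
    stop("invalid exon interval(s): end < start or start < 1")
  }
  if (!is.null(cds)) {
    cds <- as.data.frame(cds, stringsAsFactors = FALSE)
    if (nrow(cds) > 0 && any(cds$end < cds$start | cds$start < 1)) {
      stop("invalid CDS interval(s): end < start or start < 1")
    }
  } else {
    cds <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  if (!is.null(contig_universe)) {
    off <- setdiff(genes$contig_id, contig_universe)
    if (length(off) > 0) {
      stop("gene(s) on contig(s) absent from the universe: ",
           paste(off, collapse = ", "))
    }
  }
  exons <- exons[order(exons$transcript_id, exons$start, exons$end), ,
                 drop = FALSE]
  rownames(exons) <- NULL

  genes$representative <- .pick_representative(genes, transcripts, cds)

  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds, contig_universe = contig_universe,
                 warnings = warnings),
            class = "annotation_set")
}

# Representative transcript: max summed CDS length, then smallest id.
.pick_representative <- function(genes, transcripts, cds) {
  cds_len <- stats::setNames(rep(0L, nrow(transcripts)),
                             transcripts$transcript_id)
  if (nrow(cds) > 0) {
    by_tx <- tapply(cds$end - cds$start + 1L, cds$transcript_id, sum)
    cds_len[names(by_tx)] <- as.integer(by_tx)
  }
  if (nrow(transcripts) == 0) return(rep(NA_character_, nrow(genes)))
  tx <- transcripts[order(transcripts$gene_id,
                          -cds_len[transcripts$transcript_id],
                          transcripts$transcript_id), , drop = FALSE]
  first <- tx[!duplicated(tx$gene_id), , drop = FALSE]
  unname(stats::setNames(first$transcript_id, first$gene_id)[genes$gene_id])
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d genes, %d transcripts, %d exons%s\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              if (length(x$warnings) > 0)
                sprintf(" (%d parse warnings)", length(x$warnings)) else ""))
  invisible(x)
}

#' Exons of each gene's representative transcript
#'
#' @param x An `annotation_set`.
#' @return data.frame with columns `gene_id`, `transcript_id`, `start`,
#'   `end`, sorted by start within gene.
#' @export
representative_exons <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  rep_tx <- x$genes$representative
  keep <- x$exons[x$exons$transcript_id %in% rep_tx, , drop = FALSE]
  tx2gene <- stats::setNames(x$genes$gene_id, rep_tx)
  keep$gene_id <- unname(tx2gene[keep$transcript_id])
  keep[, c("gene_id", "transcript_id", "start", "end")]
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA`/`transcript`, `exon` and `CDS` features linked by
#' `ID`/`Parent` attributes into an [annotation_set()]. Parsing is
#' insensitive to feature order (the table is resolved in two passes).
#' Transcripts that carry CDS features but no exon features get exons
#' synthesized from their CDS intervals. Exons or CDS whose `Parent` does
#' not resolve to a known transcript are skipped and reported in the
#' returned object's `warnings`; a feature with `end < start` is a hard
#' error.
#'
#' @param path Path to a GFF3 file (plain or gzipped); the
#'   `##gff-version 3` directive must be present.
#' @param contig_universe Optional character vector of valid contig ids.
#' @return An [annotation_set()].
#' @export
read_gff3 <- function(path, contig_universe = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1)
  close(con)
  if (length(first) == 0 || !grepl("^##gff-version\\s+3", first)) {
    stop("missing ##gff-version 3 directive in ", path)
  }
  g <- rtracklayer::readGFF(path,
                            columns = c("seqid", "type", "start", "end",
                                        "strand"),
                            tags = c("ID", "Parent"))
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  if (nrow(g) > 0 && any(g$end < g$start)) {
    stop("feature with end < start in ", path)
  }
  g$type <- as.character(g$type)
  g$Parent1 <- vapply(g$Parent, function(p)
    if (length(p) == 0) NA_character_ else as.character(p[[1]]),
    character(1))

  warnings <- character()
  genes_raw <- g[g$type == "gene", , drop = FALSE]
  tx_raw <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  ex_raw <- g[g$type == "exon", , drop = FALSE]
  cds_raw <- g[g$type == "CDS", , drop = FALSE]

  genes <- data.frame(gene_id = genes_raw$ID,
                      contig_id = as.character(genes_raw$seqid),
                      strand = as.character(genes_raw$strand),
                      stringsAsFactors = FALSE)
  keep_tx <- tx_raw$Parent1 %in% genes$gene_id
  if (any(!keep_tx)) {
    warnings <- c(warnings, sprintf(
      "transcript %s skipped: Parent gene %s not found",
      tx_raw$ID[!keep_tx], tx_raw$Parent1[!keep_tx]))
  }
  transcripts <- data.frame(transcript_id = tx_raw$ID[keep_tx],
                            gene_id = tx_raw$Parent1[keep_tx],
                            stringsAsFactors = FALSE)

  take_children <- function(raw, what) {
    keep <- raw$Parent1 %in% transcripts$transcript_id
    if (any(!keep)) {
      warnings <<- c(warnings, sprintf(
        "%s at %s:%d-%d skipped: Parent transcript %s not found",
        what, as.character(raw$seqid[!keep]), raw$start[!keep],
        raw$end[!keep], raw$Parent1[!keep]))
    }
    data.frame(transcript_id = raw$Parent1[keep],
               start = as.integer(raw$start[keep]),
               end = as.integer(raw$end[keep]),
               stringsAsFactors = FALSE)
  }
  exons <- take_children(ex_raw, "exon")
  cds <- take_children(cds_raw, "CDS")

  # transcripts with CDS but no exon features: exons synthesized from CDS
  no_exon <- setdiff(unique(cds$transcript_id), unique(exons$transcript_id))
  if (length(no_exon) > 0) {
    exons <- rbind(exons, cds[cds$transcript_id %in% no_exon, , drop = FALSE])
  }

  annotation_set(genes, transcripts, exons, cds,
                 contig_universe = contig_universe, warnings = warnings)
}
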