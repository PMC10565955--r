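# Taxon-based contig decontamination.
#
# Each contig is assigned to the taxon (at a chosen rank) with the largest
# summed alignment bitscore across its hits ("best-sum" aggregation, robust
# to fragmented alignments), then the assembly is filtered to contigs whose
# assigned lineage intersects a keep set (default: Metazoa), optionally
# retaining contigs with no hits at all.

#' Assign a taxon to each contig from alignment hits
#'
#' Bitscores are summed per taxon name at `rank`; the taxon with the largest
#' sum wins. Ties are broken toward a lineage containing `"Metazoa"`, then
#' lexicographically by name. Contigs listed in `contig_ids` but absent from
#' the hit table are assigned `"no-hit"` with score 0. Hits whose taxid is
#' missing from the taxonomy, or whose lineage lacks `rank`, fall into an
#' "unresolved" bucket reported via the `"unresolved"` attribute rather than
#' silently defaulting.
#'
#' @param hits Hit table as returned by [read_hits_tsv()] (queries are
#'   contig ids).
#' @param taxonomy A [taxonomy_map()].
#' @param rank Assignment rank, one of the taxonomy's rank columns
#'   (default `"phylum"`).
#' @param contig_ids Optional character vector of all contigs that need a
#'   verdict (e.g. `contig_ids(assembly)`); defaults to the queries seen in
#'   `hits`.
#' @return data.frame of class `"contig_verdicts"` with columns
#'   `contig_id`, `assigned_name`, `assigned_rank`, `score` and `lineage`
#'   (semicolon-joined rank names, `""` for no-hit); attribute
#'   `"unresolved"` counts hits that could not be placed.
#' @export
assign_taxa <- function(hits, taxonomy, rank = "phylum", contig_ids = NULL) {
  stopifnot(inherits(taxonomy, "taxonomy_map"))
  if (!rank %in% names(taxonomy)) stop("rank '", rank, "' not in taxonomy map")
  if (is.null(contig_ids)) contig_ids <- unique(hits$query_id)

  idx <- match(hits$subject_taxid, taxonomy$taxid)
  unresolved <- sum(is.na(idx))
  name_at_rank <- ifelse(is.na(idx), NA, taxonomy[[rank]][idx])
  no_rank <- !is.na(idx) & (is.na(name_at_rank) | !nzchar(name_at_rank))
  unresolved <- unresolved + sum(no_rank)
  usable <- !is.na(idx) & !no_rank

  kingdom <- taxonomy$kingdom[idx]
  lineage_of <- function(i) {
    ranks <- setdiff(names(taxonomy), "taxid")
    vals <- unlist(taxonomy[i, ranks], use.names = FALSE)
    paste(vals[!is.na(vals) & nzchar(vals)], collapse = ";")
  }

  verdicts <- data.frame(contig_id = contig_ids,
                         assigned_name = "no-hit",
                         assigned_rank = rank, score = 0,
                         lineage = "", stringsAsFactors = FALSE)
  if (any(usable)) {
    h <- data.frame(q = hits$query_id[usable], name = name_at_rank[usable],
                    bs = hits$bitscore[usable],
                    metazoa = !is.na(kingdom[usable]) &
                      kingdom[usable] == "Metazoa",
                    taxrow = idx[usable], stringsAsFactors = FALSE)
    agg <- stats::aggregate(bs ~ q + name, data = h, FUN = sum)
    meta <- stats::aggregate(metazoa ~ q + name, data = h, FUN = any)
    agg$metazoa <- meta$metazoa[match(paste(agg$q, agg$name),
                                      paste(meta$q, meta$name))]
    # deterministic winner: score desc, then metazoan lineages, then name
    agg <- agg[order(agg$q, -agg$bs, !agg$metazoa, agg$name), , drop = FALSE]
    best <- agg[!duplicated(agg$q), , drop = FALSE]
    hit_row <- match(best$name, taxonomy[[rank]])
    best$lineage <- vapply(hit_row, lineage_of, character(1))
    m <- match(best$q, verdicts$contig_id)
    ok <- !is.na(m)
    verdicts$assigned_name[m[ok]] <- best$name[ok]
    verdicts$score[m[ok]] <- best$bs[ok]
    verdicts$lineage[m[ok]] <- best$lineage[ok]
  }
  attr(verdicts, "unresolved") <- unresolved
  class(verdicts) <- c("contig_verdicts", "data.frame")
  verdicts
}

#' Filter an assembly by taxon verdicts
#'
#' A contig is kept iff its assigned lineage (any rank, or the assigned
#' name itself) intersects `keep_lineages`, or it has no hit and
#' `keep_no_hit` is `TRUE`. Contigs in `exclude_ids` are always dropped
#' (e.g. a manually curated mitochondrial-contig list).
#'
#' @param x An [assembly()].
#' @param verdicts A `"contig_verdicts"` table covering every contig of `x`.
#' @param keep_lineages Character vector of taxon names to keep (default
#'   `"Metazoa"`).
#' @param keep_no_hit Keep contigs without any hit? Default `TRUE`.
#' @param exclude_ids Contig ids to drop unconditionally.
#' @return List of class `"decontam_result"` with `assembly` (the kept
#'   contigs) and `report` (a `"decontam_report"`: per-contig verdicts with
#'   `kept` and `length`, aggregate kept/dropped counts and bp, and the
#'   contaminant [taxon_breakdown()]).
#' @export
filter_assembly <- function(x, verdicts, keep_lineages = "Metazoa",
                            keep_no_hit = TRUE, exclude_ids = character()) {
  stopifnot(inherits(x, "assembly"), inherits(verdicts, "contig_verdicts"))
  ids <- contig_ids(x)
  unknown <- setdiff(verdicts$contig_id, ids)
  if (length(unknown) > 0) {
    stop("verdict(s) for unknown contig(s): ", paste(unknown, collapse = ", "))
  }
  uncovered <- setdiff(ids, verdicts$contig_id)
  if (length(uncovered) > 0) {
    stop("contig(s) without verdict: ", paste(uncovered, collapse = ", "))
  }
  v <- verdicts[match(ids, verdicts$contig_id), , drop = FALSE]
  lineage_sets <- strsplit(v$lineage, ";", fixed = TRUE)
  keep_tax <- mapply(function(lin, name) {
    name %in% keep_lineages || any(lin %in% keep_lineages)
  }, lineage_sets, v$assigned_name)
  is_nohit <- v$assigned_name == "no-hit"
  kept <- (keep_tax | (is_nohit & keep_no_hit)) & !(ids %in% exclude_ids)

  v$kept <- kept
  v$length <- as.numeric(contig_lengths(x)[ids])
  aggregate <- list(kept_contigs = sum(kept), dropped_contigs = sum(!kept),
                    kept_bp = sum(v$length[kept]),
                    dropped_bp = sum(v$length[!kept]),
                    no_hit_fraction = mean(is_nohit))
  report <- structure(list(verdicts = v, aggregate = aggregate,
                           breakdown = taxon_breakdown(v)),
                      class = "decontam_report")
  structure(list(assembly = subset_assembly(x, ids[kept]), report = report),
            class = "decontam_result")
}

#' Contaminant taxon breakdown
#'
#' Tabulates the dropped contigs per assigned taxon: contig count, bp, and
#' percent of total dropped bp, sorted by bp descending.
#'
#' @param verdicts A `"contig_verdicts"` data.frame carrying `kept` and
#'   `length` columns (as found in a `decontam_report`).
#' @return data.frame with columns `taxon`, `n_contigs`, `bp`,
#'   `pct_dropped_bp`; empty when nothing was dropped.
#' @export
taxon_breakdown <- function(verdicts) {
  stopifnot(is.data.frame(verdicts),
            all(c("kept", "length", "assigned_name") %in% names(verdicts)))
  dropped <- verdicts[!verdicts$kept, , drop = FALSE]
  if (nrow(dropped) == 0) {
    return(data.frame(taxon = character(), n_contigs = integer(),
                      bp = numeric(), pct_dropped_bp = numeric()))
  }
  bp <- tapply(dropped$length, dropped$assigned_name, sum)
  n <- tapply(dropped$length, dropped$assigned_name, length)
  out <- data.frame(taxon = names(bp), n_contigs = as.integer(n),
                    bp = as.numeric(bp),
                    pct_dropped_bp = 100 * as.numeric(bp) / sum(dropped$length),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$bp, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
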