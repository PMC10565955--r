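# Assembly contiguity and composition summaries.
#
# Conventions: N50 is the length of the contig at which the cumulative
# length, accumulating from longest to shortest, first reaches half the
# total assembly length (not half of an external reference size). Lowercase
# marks soft-masked bases; N and n both count as "N", and a lowercase n
# counts toward BOTH the N tally and the masked tally. Internal values are
# plain bp; unit formatting (Mb/kb) happens only in comparison_table().

#' Summarize an assembly
#'
#' Computes the contiguity and composition metrics of a standard
#' cross-genome comparison table: total length, contig count, longest and
#' mean contig length, N50, N content, soft-masked fraction and GC of
#' non-N bases.
#'
#' @param x An [assembly()]; must be non-empty.
#' @return A list of class `"assembly_summary"` with elements
#'   `total_length`, `n_contigs`, `longest`, `mean_length`, `n50` (all bp),
#'   `n_count` (bp of N/n), `n_percent`, `masked_percent` (percent of total
#'   length), and `gc_fraction` (G+C over non-N bases).
#' @examples
#' asm <- assembly(c(a = "ACGTACGTAC", b = "acgtN", c = "GGG"))
#' summarize_assembly(asm)$n50
#' @export
summarize_assembly <- function(x) {
  stopifnot(inherits(x, "assembly"))
  if (length(x) == 0) stop("empty assembly")
  lens <- contig_lengths(x)
  total <- sum(as.numeric(lens))
  freq <- Biostrings::letterFrequency(x$seqs, letters = ASSEMBLY_ALPHABET)
  tot_freq <- colSums(freq)
  lower <- sum(tot_freq[tolower(IUPAC_NT)])
  n_count <- sum(tot_freq[c("N", "n")])
  gc <- sum(tot_freq[c("G", "C", "g", "c")])
  non_n <- total - n_count
  structure(list(
    total_length = total,
    n_contigs = length(lens),
    longest = max(lens),
    mean_length = total / length(lens),
    n50 = .n50(lens),
    n_count = n_count,
    n_percent = 100 * n_count / total,
    masked_percent = 100 * lower / total,
    gc_fraction = if (non_n > 0) gc / non_n else NA_real_
  ), class = "assembly_summary")
}

.n50 <- function(lens) {
  lens <- sort(as.numeric(lens), decreasing = TRUE)
  cum <- cumsum(lens)
  lens[which(cum >= sum(lens) / 2)[1]]
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat(sprintf(paste0("<assembly_summary> %d contigs, %.0f bp, N50 %.0f bp, ",
                     "N %.3f%%, masked %.2f%%\n"),
              x$n_contigs, x$total_length, x$n50, x$n_percent,
              x$masked_percent))
  invisible(x)
}

#' Cumulative assembly length curve
#'
#' Contigs are ranked from longest to shortest; the curve gives the
#' cumulative assembled length at each rank and is the standard visual
#' comparison of assembly contiguity.
#'
#' @param x An [assembly()]; must be non-empty.
#' @return data.frame with columns `rank`, `length` (contig length at that
#'   rank) and `cumulative` (bp); the final `cumulative` equals the total
#'   assembly length.
#' @export
cumulative_length_curve <- function(x) {
  stopifnot(inherits(x, "assembly"))
  if (length(x) == 0) stop("empty assembly")
  lens <- sort(as.numeric(contig_lengths(x)), decreasing = TRUE)
  data.frame(rank = seq_along(lens), length = lens, cumulative = cumsum(lens))
}

#' Soft-masked fraction of an assembly
#'
#' @param x An [assembly()] read with case preserved.
#' @return Percentage (0-100) of bases that are lowercase.
#' @export
masked_fraction <- function(x) {
  stopifnot(inherits(x, "assembly"))
  freq <- Biostrings::letterFrequency(x$seqs,
                                      letters = paste(tolower(IUPAC_NT),
                                                      collapse = ""))
  100 * sum(freq) / sum(as.numeric(contig_lengths(x)))
}
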