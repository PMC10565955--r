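# Assembly container and FASTA I/O.
#
# Sequences are held as a Biostrings::BStringSet because soft-masking is
# encoded as lowercase in FASTA and must survive the round trip (a
# DNAStringSet would fold case).

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")
ASSEMBLY_ALPHABET <- c(IUPAC_NT, tolower(IUPAC_NT))

#' Construct a genome assembly
#'
#' An assembly is an ordered collection of uniquely named contigs whose
#' sequences use IUPAC nucleotide codes in either case; lowercase letters
#' mark soft-masked (repeat-derived) bases and `N`/`n` mark gap fill.
#'
#' @param seqs A named character vector or a [Biostrings::BStringSet];
#'   names are contig ids (must be unique and non-empty), values the
#'   sequences with case preserved.
#' @return An object of class `"assembly"` wrapping a `BStringSet`.
#' @examples
#' asm <- assembly(c(c1 = "ACGTacgtNN", c2 = "GGGC"))
#' contig_lengths(asm)
#' @export
assembly <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- Biostrings::BStringSet(seqs)
  }
  if (!methods::is(seqs, "BStringSet")) {
    stop("`seqs` must be a named character vector or a BStringSet")
  }
  ids <- names(seqs)
  if (length(seqs) > 0 &&
      (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))) {
    stop("every contig must have a non-empty id")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate contig id(s): ", paste(dup, collapse = ", "))
  }
  if (any(Biostrings::width(seqs) < 1)) {
    empty <- ids[Biostrings::width(seqs) < 1]
    stop("empty sequence record(s): ", paste(empty, collapse = ", "))
  }
  bad <- .non_iupac_count(seqs)
  if (any(bad > 0)) {
    stop("non-IUPAC characters in contig(s): ",
         paste(ids[bad > 0], collapse = ", "))
  }
  structure(list(seqs = seqs), class = "assembly")
}

.non_iupac_count <- function(seqs) {
  freq <- Biostrings::letterFrequency(seqs, letters = ASSEMBLY_ALPHABET)
  Biostrings::width(seqs) - rowSums(freq)
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d contigs, %s bp total\n",
              length(x$seqs), format(sum(contig_lengths(x)), big.mark = ",")))
  invisible(x)
}

#' @export
length.assembly <- function(x) length(x$seqs)

#' Contig ids and lengths of an assembly
#' @param x An `assembly`.
#' @return `contig_ids()`: character vector; `contig_lengths()`: named
#'   integer vector of sequence lengths in bp.
#' @export
contig_ids <- function(x) {
  stopifnot(inherits(x, "assembly"))
  names(x$seqs)
}

#' @rdname contig_ids
#' @export
contig_lengths <- function(x) {
  stopifnot(inherits(x, "assembly"))
  stats::setNames(Biostrings::width(x$seqs), names(x$seqs))
}

#' Read an assembly from FASTA
#'
#' The id of each contig is the header token before the first whitespace;
#' sequence case is preserved so that soft-masking information is kept.
#' Plain and gzip-compressed files are accepted.
#'
#' @param path Path to a FASTA file (optionally `.gz`).
#' @return An [assembly()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  assembly(seqs)
}

#' Write an assembly to FASTA
#'
#' @param x An [assembly()].
#' @param path Output path.
#' @param width Line wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "assembly"))
  Biostrings::writeXStringSet(x$seqs, filepath = path, width = width)
  invisible(path)
}

#' Subset an assembly by contig id
#' @param x An `assembly`.
#' @param ids Contig ids to keep, in the order given.
#' @return An `assembly` with the selected contigs.
#' @export
subset_assembly <- function(x, ids) {
  stopifnot(inherits(x, "assembly"))
  missing <- setdiff(ids, contig_ids(x))
  if (length(missing) > 0) {
    stop("unknown contig id(s): ", paste(missing, collapse = ", "))
  }
  assembly(x$seqs[ids])
}
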