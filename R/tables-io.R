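# Tabular inputs: orthogroup tables (OrthoFinder Orthogroups.tsv dialect),
# 13-column alignment hit tables, taxid lineage maps, clade maps, coverage.

#' Construct an orthogroup count table
#'
#' @param counts Integer matrix, orthogroups in rows (rownames = orthogroup
#'   ids), species in columns (colnames = species ids); entries are gene
#'   counts per orthogroup and species.
#' @return An object of class `"orthogroup_table"` (the validated matrix).
#' @export
orthogroup_table <- function(counts) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts))) {
    stop("counts must have orthogroup rownames and species colnames")
  }
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup) > 0) stop("duplicate orthogroup id(s): ",
                            paste(dup, collapse = ", "))
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative integers")
  }
  if (nrow(counts) > 0 && any(rowSums(counts) < 1)) {
    stop("orthogroup(s) with total count 0: ",
         paste(rownames(counts)[rowSums(counts) < 1], collapse = ", "))
  }
  structure(counts, class = c("orthogroup_table", "matrix", "array"))
}

#' Read an orthogroup membership table
#'
#' Reads the tab-separated "orthogroup x species -> gene list" dialect used
#' by orthology-clustering tools: a header row of species ids (first column
#' is the orthogroup id), one row per orthogroup, cells holding
#' comma-separated gene ids or empty. The gene count of a cell is its number
#' of comma-separated tokens after trimming whitespace; an empty or
#' whitespace-only cell counts 0.
#'
#' @param path Path to the TSV (plain or gzipped).
#' @param species_list Optional explicit species universe; species absent
#'   from the file header are added as all-zero columns.
#' @return An [orthogroup_table()].
#' @export
read_orthogroups_tsv <- function(path, species_list = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 2) stop("orthogroup table needs an id column plus >=1 species")
  og_ids <- tab[[1]]
  dup <- unique(og_ids[duplicated(og_ids)])
  if (length(dup) > 0) stop("duplicate orthogroup id(s): ",
                            paste(dup, collapse = ", "))
  species <- colnames(tab)[-1]
  count_cell <- function(cell) {
    toks <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    sum(nzchar(toks))
  }
  counts <- vapply(seq_along(species) + 1L, function(j)
    vapply(tab[[j]], count_cell, integer(1), USE.NAMES = FALSE),
    integer(nrow(tab)))
  counts <- matrix(as.integer(counts), nrow = nrow(tab),
                   ncol = length(species),
                   dimnames = list(og_ids, species))
  if (!is.null(species_list)) {
    extra <- setdiff(species_list, species)
    if (length(extra) > 0) {
      counts <- cbind(counts, matrix(0L, nrow(counts), length(extra),
                                     dimnames = list(NULL, extra)))
    }
    counts <- counts[, union(species, species_list), drop = FALSE]
  }
  orthogroup_table(counts)
}

HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity", "aln_length",
                 "mismatches", "gap_opens", "qstart", "qend", "sstart",
                 "send", "evalue", "bitscore", "subject_taxid")

.empty_hits <- function() {
  out <- data.frame(query_id = character(), subject_id = character(),
                    percent_identity = numeric(), aln_length = numeric(),
                    mismatches = numeric(), gap_opens = numeric(),
                    qstart = numeric(), qend = numeric(),
                    sstart = numeric(), send = numeric(),
                    evalue = numeric(), bitscore = numeric(),
                    subject_taxid = integer(), stringsAsFactors = FALSE)
  out
}

#' Read a tabular alignment hit table
#'
#' Reads the 12-column tabular BLAST/diamond format (outfmt 6) with an
#' added 13th column holding the subject taxid. Non-numeric values in a
#' numeric field are a hard error reporting the offending line.
#'
#' @param path Path to the TSV (plain or gzipped); no header row.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `aln_length`, `mismatches`, `gap_opens`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`, `subject_taxid`.
#'   An empty file gives an empty (0-row) table.
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (length(lines) == 0) return(.empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 13)) {
    stop("line ", which(nf != 13)[1], ": expected 13 tab-separated fields, got ",
         nf[nf != 13][1])
  }
  m <- do.call(rbind, parts)
  hits <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                     stringsAsFactors = FALSE)
  num_cols <- c(percent_identity = 3, aln_length = 4, mismatches = 5,
                gap_opens = 6, qstart = 7, qend = 8, sstart = 9, send = 10,
                evalue = 11, bitscore = 12, subject_taxid = 13)
  for (nm in names(num_cols)) {
    v <- suppressWarnings(as.numeric(m[, num_cols[[nm]]]))
    if (any(is.na(v))) {
      stop("line ", which(is.na(v))[1], ": non-numeric ", nm, " '",
           m[which(is.na(v))[1], num_cols[[nm]]], "'")
    }
    hits[[nm]] <- v
  }
  hits$subject_taxid <- as.integer(hits$subject_taxid)
  if (any(hits$evalue < 0)) stop("negative evalue")
  hits
}

#' Read a taxid -> ranked lineage map
#'
#' @param path TSV with a header row; columns `taxid` plus one column per
#'   rank (at least `superkingdom`, `kingdom`, `phylum`). Empty cells mean
#'   the rank is absent from that lineage.
#' @return data.frame of class `"taxonomy_map"`.
#' @export
read_taxonomy_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tax <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "")
  taxonomy_map(tax)
}

#' Construct a taxonomy map
#'
#' @param tax data.frame with a `taxid` column and one column per rank.
#' @return data.frame of class `"taxonomy_map"`.
#' @export
taxonomy_map <- function(tax) {
  tax <- as.data.frame(tax, stringsAsFactors = FALSE)
  if (!"taxid" %in% names(tax)) stop("taxonomy map needs a 'taxid' column")
  needed <- c("superkingdom", "kingdom", "phylum")
  miss <- setdiff(needed, names(tax))
  if (length(miss) > 0) stop("taxonomy map missing rank column(s): ",
                             paste(miss, collapse = ", "))
  tax$taxid <- as.integer(tax$taxid)
  dup <- unique(tax$taxid[duplicated(tax$taxid)])
  if (length(dup) > 0) stop("duplicate taxid(s): ", paste(dup, collapse = ", "))
  class(tax) <- c("taxonomy_map", "data.frame")
  tax
}

#' Read a species -> clade map
#'
#' @param path TSV with header `species`, `clade` and optionally `subclade`.
#' @return Named character vector species -> clade; when a `subclade`
#'   column is present it is attached as the `"subclade"` attribute (a named
#'   character vector).
#' @export
read_clades_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("species", "clade") %in% names(tab))) {
    stop("clade map needs 'species' and 'clade' columns")
  }
  clades <- stats::setNames(tab$clade, tab$species)
  if ("subclade" %in% names(tab)) {
    attr(clades, "subclade") <- stats::setNames(tab$subclade, tab$species)
  }
  clades
}

#' Read a per-contig coverage/GC table
#'
#' @param path TSV with header `contig_id`, `coverage`, `gc`.
#' @return data.frame with those columns; coverage must be >= 0 and gc in
#'   \[0, 1\].
#' @export
read_coverage_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (!all(c("contig_id", "coverage", "gc") %in% names(tab))) {
    stop("coverage table needs 'contig_id', 'coverage' and 'gc' columns")
  }
  if (any(tab$coverage < 0)) stop("negative coverage")
  if (any(tab$gc < 0 | tab$gc > 1)) stop("gc outside [0, 1]")
  tab
}
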