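# Orthogroup clade-partition analysis of gene content.
#
# An orthogroup is "present" in a clade iff at least one species of that
# clade carries >= 1 gene of it. The partition assigns each orthogroup to
# the subset of clades where it is present; shared/exclusive statistics,
# the metazoan and bilaterian shared sets, and missing fractions all derive
# from that partition. The metazoan set (outgroup + >= 1 ingroup clade) and
# the bilaterian set (>= 2 ingroup clades, no outgroup) are disjoint by
# construction and together make up exactly the orthogroups present in
# >= 2 clades.

#' Partition orthogroups by clade presence
#'
#' @param table An [orthogroup_table()].
#' @param clades Named character vector species -> clade (see
#'   [read_clades_tsv()]); every species in the table must be assigned.
#' @return Logical matrix of class `"clade_partition"`: orthogroups x
#'   clades, `TRUE` where at least one species of the clade has count >= 1.
#' @export
partition_by_clade <- function(table, clades) {
  stopifnot(inherits(table, "orthogroup_table"))
  species <- colnames(table)
  missing <- species[!species %in% names(clades)]
  if (length(missing) > 0) {
    stop("species without clade assignment: ", paste(missing, collapse = ", "))
  }
  labels <- sort(unique(unname(clades[species])))
  part <- vapply(labels, function(cl) {
    sp <- species[clades[species] == cl]
    rowSums(table[, sp, drop = FALSE] >= 1L) > 0
  }, logical(nrow(table)))
  part <- matrix(part, nrow = nrow(table),
                 dimnames = list(rownames(table), labels))
  class(part) <- c("clade_partition", "matrix", "array")
  part
}

#' Per-clade presence and exclusivity
#'
#' @param partition A `"clade_partition"`.
#' @return data.frame with one row per clade: `clade`, `present` (number of
#'   orthogroups present in the clade), `exclusive` (present in that clade
#'   only) and `pct_exclusive` (100 * exclusive / present; `NA` for a clade
#'   with nothing present, flagged in `absent_clade`).
#' @export
exclusivity_stats <- function(partition) {
  stopifnot(inherits(partition, "clade_partition"))
  if (nrow(partition) == 0) stop("empty partition")
  n_clades <- rowSums(partition)
  present <- colSums(partition)
  exclusive <- colSums(partition & n_clades == 1)
  data.frame(clade = colnames(partition),
             present = as.integer(present),
             exclusive = as.integer(exclusive),
             pct_exclusive = ifelse(present > 0, 100 * exclusive / present,
                                    NA_real_),
             absent_clade = present == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Metazoan-shared and bilaterian-shared orthogroup sets
#'
#' The metazoan set holds orthogroups present in the outgroup clade and in
#' at least one other clade; the bilaterian set holds orthogroups absent
#' from the outgroup but present in at least two of the remaining clades.
#' The two sets are disjoint and their union is exactly the orthogroups
#' present in two or more clades.
#'
#' @param partition A `"clade_partition"` whose clade labels include
#'   `outgroup`.
#' @param outgroup The outgroup clade label (default `"Cnidaria"`).
#' @return List with `metazoan_set`, `bilaterian_set` (character vectors of
#'   orthogroup ids) and `shared_total` (their combined size).
#' @export
shared_sets <- function(partition, outgroup = "Cnidaria") {
  stopifnot(inherits(partition, "clade_partition"))
  if (!outgroup %in% colnames(partition)) {
    stop("outgroup clade '", outgroup, "' not in partition")
  }
  n_clades <- rowSums(partition)
  has_out <- partition[, outgroup]
  metazoan <- rownames(partition)[has_out & n_clades >= 2]
  bilaterian <- rownames(partition)[!has_out & n_clades >= 2]
  list(metazoan_set = metazoan, bilaterian_set = bilaterian,
       shared_total = length(metazoan) + length(bilaterian))
}

#' Fraction of a gene set missing from a clade
#'
#' @param partition A `"clade_partition"`.
#' @param gene_set Character vector of orthogroup ids, a subset of the
#'   partition's rownames (e.g. a set from [shared_sets()]); must be
#'   non-empty.
#' @param clade Clade label.
#' @return Percentage (0-100) of `gene_set` members where `clade` is absent.
#' @export
missing_fraction <- function(partition, gene_set, clade) {
  stopifnot(inherits(partition, "clade_partition"))
  if (length(gene_set) == 0) stop("empty gene set")
  bad <- setdiff(gene_set, rownames(partition))
  if (length(bad) > 0) stop("orthogroup(s) not in partition: ",
                            paste(bad, collapse = ", "))
  if (!clade %in% colnames(partition)) stop("unknown clade: ", clade)
  100 * sum(!partition[gene_set, clade]) / length(gene_set)
}

#' Orthogroup sharing between two subclades of a focal clade
#'
#' Over the orthogroups present in the focal clade, counts those present in
#' both subclades ("shared") and those unique to each; the three
#' percentages sum to 100 within rounding.
#'
#' @param table An [orthogroup_table()].
#' @param clades Named character vector species -> clade.
#' @param subclades Named character vector species -> subclade for the
#'   focal clade's species; must define exactly two subclades, each with at
#'   least one species.
#' @param focal_clade Clade label to analyse (e.g. `"Acoelomorpha"`).
#' @return data.frame with rows `shared`, `unique_<A>`, `unique_<B>` and
#'   columns `category`, `n`, `pct`.
#' @export
within_clade_sharing <- function(table, clades, subclades, focal_clade) {
  stopifnot(inherits(table, "orthogroup_table"))
  species <- colnames(table)
  focal_sp <- species[!is.na(clades[species]) & clades[species] == focal_clade]
  if (length(focal_sp) == 0) stop("no species of clade ", focal_clade)
  sub <- subclades[focal_sp]
  if (any(is.na(sub))) {
    stop("focal species without subclade: ",
         paste(focal_sp[is.na(sub)], collapse = ", "))
  }
  labs <- sort(unique(unname(sub)))
  if (length(labs) != 2) stop("focal clade must split into exactly 2 subclades")
  sp_a <- focal_sp[sub == labs[1]]
  sp_b <- focal_sp[sub == labs[2]]
  in_a <- rowSums(table[, sp_a, drop = FALSE] >= 1L) > 0
  in_b <- rowSums(table[, sp_b, drop = FALSE] >= 1L) > 0
  focal_present <- in_a | in_b
  n <- sum(focal_present)
  if (n == 0) stop("no orthogroup present in clade ", focal_clade)
  counts <- c(shared = sum(in_a & in_b),
              sum(in_a & !in_b), sum(!in_a & in_b))
  data.frame(category = c("shared", paste0("unique_", labs[1]),
                          paste0("unique_", labs[2])),
             n = as.integer(counts), pct = 100 * counts / n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full gene-content summary
#'
#' Bundles the clade partition, the 15 Venn class counts, per-clade
#' exclusivity, the shared sets and the per-clade missing fractions over
#' each shared set.
#'
#' @inheritParams partition_by_clade
#' @inheritParams shared_sets
#' @return List of class `"content_summary"` with `partition`,
#'   `venn_counts` (named by "+"-joined clade subsets), `exclusivity`,
#'   `shared` (from [shared_sets()]), `pct_shared` (shared_total as percent
#'   of all orthogroups) and `missing` (data.frame clade x gene set with
#'   percent missing and percent present).
#' @export
gene_content_summary <- function(table, clades, outgroup = "Cnidaria") {
  partition <- partition_by_clade(table, clades)
  classes <- apply(partition, 1, function(r)
    paste(colnames(partition)[r], collapse = "+"))
  venn <- table(classes)
  excl <- exclusivity_stats(partition)
  sets <- shared_sets(partition, outgroup)
  ingroup <- setdiff(colnames(partition), outgroup)
  missing <- do.call(rbind, lapply(ingroup, function(cl) {
    data.frame(clade = cl,
               set = c("metazoan", "bilaterian"),
               pct_missing = c(missing_fraction(partition, sets$metazoan_set, cl),
                               missing_fraction(partition, sets$bilaterian_set, cl)),
               stringsAsFactors = FALSE)
  }))
  missing$pct_present <- 100 - missing$pct_missing
  structure(list(partition = partition,
                 venn_counts = stats::setNames(as.integer(venn), names(venn)),
                 exclusivity = excl, shared = sets,
                 pct_shared = 100 * sets$shared_total / nrow(partition),
                 missing = missing),
            class = "content_summary")
}
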