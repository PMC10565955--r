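# Seeded synthetic assembly generator.
#
# Emulates the statistical structure the downstream metrics depend on:
# log-normal contig lengths, N-run gap fill, soft-masked repeat tracts
# (lowercase), and a planted fraction of contaminant contigs with shifted
# GC and read coverage and foreign taxon labels. Sequence content is i.i.d.
# with configurable GC; no repeat-family realism beyond the masked tracts,
# which is sufficient for every statistic computed on it. Every generator
# in the package takes an explicit seed and is byte-deterministic under it.

#' Synthetic taxonomy palette
#'
#' A small taxid -> lineage table covering a metazoan host phylum and the
#' typical contaminant groups of an invertebrate genome project (bacteria,
#' fungi, algae). Bacterial lineages have no kingdom rank, which exercises
#' the unresolved-rank path of [assign_taxa()] at `rank = "kingdom"`.
#'
#' @return A [taxonomy_map()].
#' @export
default_taxonomy <- function() {
  taxonomy_map(data.frame(
    taxid = c(1001L, 1002L, 2001L, 2002L, 2003L, 2004L, 2005L,
              3001L, 3002L, 4001L, 4002L),
    superkingdom = c("Eukaryota", "Eukaryota", rep("Bacteria", 5),
                     rep("Eukaryota", 4)),
    kingdom = c("Metazoa", "Metazoa", rep("", 5), "Fungi", "Fungi",
                "Viridiplantae", ""),
    phylum = c("Xenacoelomorpha", "Chordata", "Proteobacteria",
               "Bacteroidetes", "Actinobacteria", "Firmicutes",
               "Cyanobacteria", "Ascomycota", "Basidiomycota",
               "Chlorophyta", "Rhodophyta"),
    stringsAsFactors = FALSE))
}

.random_seq <- function(len, gc) {
  sample(c("A", "C", "G", "T"), len, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Mask exactly `target` bases as (up to) three lowercase tracts, one per
# third of the contig; exact by construction (tract quantization only moves
# tract positions, never the total).
.mask_tracts <- function(chars, target) {
  len <- length(chars)
  if (target <= 0) return(chars)
  len3 <- len %/% 3L
  thirds <- list(c(1L, len3), c(len3 + 1L, 2L * len3), c(2L * len3 + 1L, len))
  p <- c(target %/% 3L, target %/% 3L, target - 2L * (target %/% 3L))
  for (i in 1:3) {
    if (p[i] == 0) next
    lo <- thirds[[i]][1]; hi <- thirds[[i]][2]
    slack <- (hi - lo + 1L) - p[i]
    start <- lo + sample.int(slack + 1L, 1) - 1L
    idx <- start:(start + p[i] - 1L)
    chars[idx] <- tolower(chars[idx])
  }
  chars
}

#' Simulate an assembly with planted contaminants
#'
#' @param n_contigs Number of contigs.
#' @param length_meanlog,length_sdlog Log-normal contig length parameters
#'   (bp); lengths are clamped to `min_length`.
#' @param min_length Minimum contig length in bp.
#' @param gc Host GC fraction.
#' @param contam_fraction Fraction of contigs planted as contaminants
#'   (exact count `round(contam_fraction * n_contigs)`); default 0.211, a
#'   typical contaminant load of a single-specimen invertebrate assembly
#'   where 78.9 percent of contigs are metazoan.
#' @param contam_taxa Phylum names (from [default_taxonomy()]) sampled for
#'   contaminant contigs.
#' @param contam_gc_shift GC shift applied to contaminant contigs.
#' @param host_taxon Host phylum label.
#' @param host_coverage,contam_coverage Mean read coverage of host and
#'   contaminant contigs (normal noise, sd = coverage / 8, floored at 1).
#' @param n_run_rate Expected number of N runs per contig (Poisson).
#' @param n_run_length Integer range of N-run lengths.
#' @param masked_fraction Fraction of each contig soft-masked as lowercase
#'   tracts; must lie in `[0, 1]`. Default 0.597, the repeat load typical
#'   of acoelomorph genomes.
#' @param seed Integer seed; same seed, same bytes.
#' @return List of class `"sim_assembly"`: `assembly` (an [assembly()]),
#'   `manifest` (data.frame per contig: `contig_id`, `length`, `taxon`,
#'   `is_contaminant`, `masked_bp`, `n_count`, `gc_target`, `coverage`),
#'   `coverage` (a coverage table as in [read_coverage_tsv()]) and
#'   `taxonomy`.
#' @export
simulate_assembly <- function(n_contigs = 200,
                              length_meanlog = log(3e4), length_sdlog = 0.9,
                              min_length = 1000,
                              gc = 0.38,
                              contam_fraction = 0.211,
                              contam_taxa = c("Proteobacteria",
                                              "Bacteroidetes", "Ascomycota",
                                              "Chlorophyta"),
                              contam_gc_shift = 0.15,
                              host_taxon = "Xenacoelomorpha",
                              host_coverage = 40, contam_coverage = 8,
                              n_run_rate = 0.5,
                              n_run_length = c(50L, 300L),
                              masked_fraction = 0.597,
                              seed = 1) {
  if (masked_fraction < 0 || masked_fraction > 1) {
    stop("masked_fraction must be in [0, 1]")
  }
  if (contam_fraction < 0 || contam_fraction > 1) {
    stop("contam_fraction must be in [0, 1]")
  }
  set.seed(seed)
  taxonomy <- default_taxonomy()
  bad_taxa <- setdiff(contam_taxa, taxonomy$phylum)
  if (length(bad_taxa) > 0) stop("unknown contaminant taxa: ",
                                 paste(bad_taxa, collapse = ", "))

  lens <- pmax(min_length, round(stats::rlnorm(n_contigs, length_meanlog,
                                               length_sdlog)))
  n_contam <- round(contam_fraction * n_contigs)
  is_contam <- rep(FALSE, n_contigs)
  is_contam[sample.int(n_contigs, n_contam)] <- TRUE
  taxon <- ifelse(is_contam,
                  sample(contam_taxa, n_contigs, replace = TRUE), host_taxon)
  gc_target <- ifelse(is_contam, pmin(0.95, gc + contam_gc_shift), gc)
  coverage <- pmax(1, stats::rnorm(
    n_contigs,
    mean = ifelse(is_contam, contam_coverage, host_coverage),
    sd = ifelse(is_contam, contam_coverage, host_coverage) / 8))

  ids <- sprintf("contig_%04d", seq_len(n_contigs))
  masked_bp <- integer(n_contigs)
  seqs <- character(n_contigs)
  for (i in seq_len(n_contigs)) {
    chars <- .random_seq(lens[i], gc_target[i])
    n_runs <- stats::rpois(1, n_run_rate)
    for (r in seq_len(n_runs)) {
      rl <- sample(n_run_length[1]:n_run_length[2], 1)
      if (rl >= lens[i]) next
      start <- sample.int(lens[i] - rl + 1L, 1)
      chars[start:(start + rl - 1L)] <- "N"
    }
    masked_bp[i] <- round(masked_fraction * lens[i])
    chars <- .mask_tracts(chars, masked_bp[i])
    seqs[i] <- paste(chars, collapse = "")
  }
  asm <- assembly(stats::setNames(seqs, ids))
  n_count <- as.integer(Biostrings::letterFrequency(asm$seqs, letters = "Nn"))

  manifest <- data.frame(contig_id = ids, length = lens, taxon = taxon,
                         is_contaminant = is_contam, masked_bp = masked_bp,
                         n_count = n_count, gc_target = gc_target,
                         coverage = coverage, stringsAsFactors = FALSE)
  cov_tab <- data.frame(contig_id = ids, coverage = coverage,
                        gc = gc_target, stringsAsFactors = FALSE)
  structure(list(assembly = asm, manifest = manifest, coverage = cov_tab,
                 taxonomy = taxonomy),
            class = "sim_assembly")
}

#' Simulate decontamination hit tables for an assembly
#'
#' Every contig except a planted no-hit fraction of the host contigs
#' receives 2-4 hits whose bitscore mass supports its manifest taxon;
#' optionally one weaker off-target hit is added so that best-sum
#' aggregation (not single-best-hit luck) is what recovers the truth.
#' Contaminant contigs always receive hits.
#'
#' @param sim A `"sim_assembly"` from [simulate_assembly()].
#' @param no_hit_fraction Fraction of HOST contigs left without any hit
#'   (exact count); default 0.181, a typical unannotated fraction of a
#'   non-model genome.
#' @param noise_rate Probability that a contig also gets one off-target hit
#'   (bitscore <= 100, below the 150+ on-target mass).
#' @param seed Integer seed.
#' @return List of class `"sim_hits"`: `hits` (data.frame in
#'   [read_hits_tsv()] layout), `taxonomy`, and `manifest` (the assembly
#'   manifest plus an `expected_assignment` column: the phylum, or
#'   `"no-hit"`).
#' @export
simulate_taxon_hits <- function(sim, no_hit_fraction = 0.181,
                                noise_rate = 0.3, seed = 1) {
  stopifnot(inherits(sim, "sim_assembly"))
  set.seed(seed)
  man <- sim$manifest
  taxonomy <- sim$taxonomy
  taxid_of <- stats::setNames(taxonomy$taxid, taxonomy$phylum)

  host_idx <- which(!man$is_contaminant)
  n_nohit <- round(no_hit_fraction * length(host_idx))
  nohit <- rep(FALSE, nrow(man))
  nohit[sample(host_idx, n_nohit)] <- TRUE

  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    if (nohit[i]) next
    k <- sample(2:4, 1)
    bs <- round(stats::runif(k, 150, 400), 1)
    taxids <- rep(taxid_of[[man$taxon[i]]], k)
    if (stats::runif(1) < noise_rate) {
      other <- sample(setdiff(taxonomy$phylum, man$taxon[i]), 1)
      bs <- c(bs, round(stats::runif(1, 40, 100), 1))
      taxids <- c(taxids, taxid_of[[other]])
      k <- k + 1
    }
    alen <- sample(80:400, k, replace = TRUE)
    rows[[i]] <- data.frame(
      query_id = man$contig_id[i],
      subject_id = sprintf("prot_%05d", sample.int(99999, k)),
      percent_identity = round(stats::runif(k, 55, 98), 1),
      aln_length = alen, mismatches = sample(0:40, k, replace = TRUE),
      gap_opens = sample(0:5, k, replace = TRUE),
      qstart = 1L, qend = alen * 3L, sstart = 1L, send = alen,
      evalue = signif(10^stats::runif(k, -80, -10), 3), bitscore = bs,
      subject_taxid = as.integer(taxids), stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  man$expected_assignment <- ifelse(nohit, "no-hit", man$taxon)
  structure(list(hits = hits, taxonomy = taxonomy, manifest = man),
            class = "sim_hits")
}

#' Write a hit table in 13-column tabular format
#' @param hits Hit table ([read_hits_tsv()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits[, HIT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a taxonomy map as TSV
#' @param taxonomy A [taxonomy_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  utils::write.table(as.data.frame(taxonomy), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
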