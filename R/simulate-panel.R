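# Seeded synthetic fixtures for the gene-panel analyses: per-species hit
# tables with planted presences/absences, and architecture records with
# planted clade effects for power/type-I studies of the test cascade.

#' Default presence design for the excretory-gene panel
#'
#' Family x clade presence flags reflecting the distribution of the
#' ultrafiltration excretory-system genes across animals: all nine genes in
#' deuterostomes and protostomes; everything but Osr in acoelomorphs; only
#' ZO1, Six1 and Lhx1/5 annotated in cnidarians.
#'
#' @param species Species panel (default [default_species()]).
#' @return data.frame `family` x `species` logical presence flags (long
#'   format: columns `family`, `species`, `present`).
#' @export
default_panel_design <- function(species = default_species()) {
  panel <- excretory_panel()
  present_by_clade <- list(
    Cnidaria = c("ZO1", "Six1", "Lhx1/5"),
    Acoelomorpha = setdiff(panel$family, "Osr"),
    Deuterostomia = panel$family,
    Protostomia = panel$family)
  do.call(rbind, lapply(seq_len(nrow(species)), function(i) {
    data.frame(family = panel$family, species = species$species[i],
               present = panel$family %in%
                 present_by_clade[[species$clade[i]]],
               stringsAsFactors = FALSE)
  }))
}

#' Default panel query lengths
#' @return Named numeric, family -> query protein length in aa.
#' @export
default_query_lengths <- function() {
  c("Nephrin" = 1200, "Kirrel" = 750, "ZO1" = 1700, "Eya" = 650,
    "Lhx1/5" = 400, "Osr" = 270, "POU3" = 450, "Sall" = 1000, "Six1" = 290)
}

#' Simulate per-species panel hit tables
#'
#' For each (family, species) flagged present the species' hit table gets
#' 1-3 hits passing the default thresholds (e-value <= 1e-5, query coverage
#' >= 0.5); absences get 0-2 decoy hits that fail on e-value or coverage,
#' so a presence call must apply both filters to recover the design.
#'
#' @param design Long-format presence design (default
#'   [default_panel_design()]).
#' @param query_lengths Named numeric, family -> query length (default
#'   [default_query_lengths()]).
#' @param seed Integer seed.
#' @return List of class `"sim_panel_hits"`: `hit_tables` (named list,
#'   species -> hit table), `query_lengths`, `manifest` (the design).
#' @export
simulate_panel_hits <- function(design = default_panel_design(),
                                query_lengths = default_query_lengths(),
                                seed = 1) {
  set.seed(seed)
  species <- unique(design$species)
  hit_tables <- lapply(species, function(sp) {
    sub <- design[design$species == sp, , drop = FALSE]
    rows <- lapply(seq_len(nrow(sub)), function(i) {
      fam <- sub$family[i]
      qlen <- query_lengths[[fam]]
      if (sub$present[i]) {
        k <- sample(1:3, 1)
        qstart <- sample(1:round(0.2 * qlen), k, replace = TRUE)
        qend <- qstart + round(stats::runif(k, 0.6, 0.95) * qlen)
        ev <- signif(10^stats::runif(k, -120, -20), 3)
      } else {
        k <- sample(0:2, 1)
        if (k == 0) return(NULL)
        # decoys: either weak e-value or short coverage
        weak <- stats::runif(k) < 0.5
        qstart <- sample(1:round(0.2 * qlen), k, replace = TRUE)
        qend <- qstart + round(ifelse(weak, 0.7, 0.2) * qlen)
        ev <- signif(ifelse(weak, 10^stats::runif(k, -4, -1),
                            10^stats::runif(k, -60, -20)), 3)
      }
      alen <- pmin(qend, qlen) - qstart + 1
      data.frame(query_id = fam,
                 subject_id = sprintf("%s_prot_%03d", sp,
                                      sample.int(999, k)),
                 percent_identity = round(stats::runif(k, 35, 90), 1),
                 aln_length = alen,
                 mismatches = sample(0:50, k, replace = TRUE),
                 gap_opens = sample(0:5, k, replace = TRUE),
                 qstart = qstart, qend = pmin(qend, qlen),
                 sstart = 1L, send = alen,
                 evalue = ev,
                 bitscore = round(stats::runif(k, 60, 900), 1),
                 subject_taxid = 1001L, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- .empty_hits()
    rownames(out) <- NULL
    out
  })
  names(hit_tables) <- species
  structure(list(hit_tables = hit_tables, query_lengths = query_lengths,
                 manifest = design),
            class = "sim_panel_hits")
}

#' Simulate architecture records with planted clade effects
#'
#' Draws per-record metrics from normal laws (exon counts rounded and
#' floored at 1, lengths floored at 30) with optional additive clade shifts
#' per family x metric — the ground truth for power and type-I studies of
#' [compare_clades()].
#'
#' @param families Gene families to emit.
#' @param clades Clade labels.
#' @param n_per_clade Records per family x clade.
#' @param baseline Named list of metric means
#'   (`protein_length`, `n_exons`, `mean_exon_length`).
#' @param sds Named list of metric standard deviations.
#' @param effects Optional data.frame `family`, `metric`, `clade`, `shift`
#'   (additive, same units as the metric).
#' @param seed Integer seed.
#' @return List of class `"sim_records"`: `records` (architecture-record
#'   data.frame) and `manifest` (the effects table, possibly empty).
#' @export
simulate_architecture_records <- function(families = excretory_panel()$family,
                                          clades = CLADE_ORDER,
                                          n_per_clade = 10,
                                          baseline = list(
                                            protein_length = 500,
                                            n_exons = 5,
                                            mean_exon_length = 150),
                                          sds = list(protein_length = 60,
                                                     n_exons = 1.5,
                                                     mean_exon_length = 20),
                                          effects = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(effects)) {
    effects <- data.frame(family = character(), metric = character(),
                          clade = character(), shift = numeric())
  }
  rows <- list()
  for (fam in families) {
    for (cl in clades) {
      shift_of <- function(met) {
        s <- effects$shift[effects$family == fam & effects$metric == met &
                             effects$clade == cl]
        if (length(s) == 0) 0 else sum(s)
      }
      pl <- stats::rnorm(n_per_clade, baseline$protein_length +
                           shift_of("protein_length"), sds$protein_length)
      ne <- stats::rnorm(n_per_clade, baseline$n_exons +
                           shift_of("n_exons"), sds$n_exons)
      me <- stats::rnorm(n_per_clade, baseline$mean_exon_length +
                           shift_of("mean_exon_length"),
                         sds$mean_exon_length)
      rows[[paste(fam, cl)]] <- data.frame(
        species = sprintf("%s_sp%d", tolower(substr(cl, 1, 3)),
                          seq_len(n_per_clade)),
        clade = cl, family = fam,
        gene_id = sprintf("%s_%s_%d", fam, cl, seq_len(n_per_clade)),
        protein_length = pmax(30, round(pl)),
        n_exons = pmax(1, round(ne)),
        mean_exon_length = pmax(30, me), stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  structure(list(records = records, manifest = effects),
            class = "sim_records")
}
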