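# Determinism and manifest closure of the generators: every statistic the
# pipeline computes on a synthetic fixture must equal the generator's
# recorded ground truth.

test_that("generators are byte-deterministic under a seed", {
  a1 <- simulate_assembly(n_contigs = 15, seed = 9)
  a2 <- simulate_assembly(n_contigs = 15, seed = 9)
  expect_identical(as.character(a1$assembly$seqs),
                   as.character(a2$assembly$seqs))
  expect_identical(a1$manifest, a2$manifest)
  a3 <- simulate_assembly(n_contigs = 15, seed = 10)
  expect_false(identical(as.character(a1$assembly$seqs),
                         as.character(a3$assembly$seqs)))

  g1 <- simulate_annotation(a1, seed = 2)
  g2 <- simulate_annotation(simulate_assembly(n_contigs = 15, seed = 9),
                            seed = 2)
  expect_identical(g1$gff3, g2$gff3)
  expect_identical(g1$proteins, g2$proteins)

  d <- c("Cnidaria" = 20, "Acoelomorpha+Protostomia" = 10)
  o1 <- simulate_orthogroups(design = d, seed = 5)
  o2 <- simulate_orthogroups(design = d, seed = 5)
  expect_identical(unclass(o1$table), unclass(o2$table))

  h1 <- simulate_taxon_hits(a1, seed = 4)
  h2 <- simulate_taxon_hits(a1, seed = 4)
  expect_identical(h1$hits, h2$hits)

  p1 <- simulate_panel_hits(seed = 3)
  p2 <- simulate_panel_hits(seed = 3)
  expect_identical(p1$hit_tables, p2$hit_tables)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulate_assembly(masked_fraction = 1.2), "masked_fraction")
  expect_error(simulate_assembly(contam_fraction = -0.1), "contam_fraction")
  expect_error(simulate_orthogroups(design = c("Cnidaria" = 5,
                                               "Ctenophora" = 2)),
               "without species")
})

test_that("assembly summaries close against the generator manifest", {
  sa <- simulate_assembly(n_contigs = 50, masked_fraction = 0.3, seed = 13)
  man <- sa$manifest
  s <- summarize_assembly(sa$assembly)
  expect_equal(s$n_contigs, 50)
  expect_equal(s$total_length, sum(man$length))
  expect_equal(s$longest, max(man$length))
  expect_equal(s$n50, oracle_n50(man$length))
  expect_equal(s$n_count, sum(man$n_count))
  # masked tracts are exact by construction; lowercase n double-counts
  expect_equal(masked_fraction(sa$assembly),
               100 * sum(man$masked_bp) / sum(man$length))
  expect_equal(s$masked_percent, 100 * 0.3, tolerance = 0.01)
})

test_that("annotation fixtures close against their manifest through GFF3", {
  sa <- simulate_assembly(n_contigs = 20, seed = 14)
  ann <- simulate_annotation(sa, seed = 15)
  f <- write_tmp(ann$gff3, ".gff3")
  back <- read_gff3(f, contig_universe = contig_ids(sa$assembly))
  man <- ann$manifest
  expect_equal(nrow(back$genes), nrow(man))
  expect_equal(nrow(back$transcripts), nrow(man))

  epg <- exons_per_gene(back)
  expect_identical(unname(epg$counts[man$gene_id]), man$n_exons)
  il <- intron_lengths(back)
  expect_identical(sort(il$lengths), sort(unlist(man$intron_lengths)))

  # planted protein lengths: translated CDS length / 3
  expect_identical(unname(nchar(ann$proteins[paste0(man$gene_id, ".t1")])),
                   as.integer(man$protein_length))

  # extract_architecture recovers the planted exon metrics
  pmap <- data.frame(gene_id = man$gene_id[1:5], family = "Eya",
                     species = "sim", clade = "Acoelomorpha")
  rec <- extract_architecture(back, ann$proteins, pmap)
  expect_equal(rec$n_exons, man$n_exons[1:5])
  expect_equal(rec$mean_exon_length, man$mean_exon_length[1:5])
  expect_equal(rec$protein_length, as.integer(man$protein_length[1:5]))
})

test_that("orthogroup fixtures realize the configured class design exactly", {
  design <- c("Cnidaria" = 5,
              "Cnidaria+Acoelomorpha+Deuterostomia+Protostomia" = 5,
              "Acoelomorpha+Deuterostomia" = 3)
  so <- simulate_orthogroups(design = design, seed = 16)
  p <- partition_by_clade(so$table, so$clades)
  classes <- apply(p, 1, function(r) paste(sort(colnames(p)[r]),
                                           collapse = "+"))
  canon <- vapply(strsplit(so$manifest$class, "+", fixed = TRUE),
                  function(s) paste(sort(s), collapse = "+"), character(1))
  expect_identical(unname(classes[so$manifest$orthogroup]), canon)
  expect_equal(sum(classes == "Cnidaria"), 5)

  # acoelomorph subclade categories are realized as planted
  big <- simulate_orthogroups(seed = 17)
  man <- big$manifest
  sub <- attr(big$clades, "subclade")
  w <- within_clade_sharing(big$table, big$clades, sub, "Acoelomorpha")
  cat_n <- table(man$acoelomorph_category)
  expect_equal(w$n[w$category == "shared"], unname(cat_n["shared"]))
  expect_equal(w$n[w$category == "unique_Acoela"],
               unname(cat_n["acoela_only"]))
  expect_equal(w$n[w$category == "unique_Nemertodermatida"],
               unname(cat_n["nem_only"]))
})

test_that("taxon hits lead assignment back to the planted truth", {
  sa <- simulate_assembly(n_contigs = 100, seed = 18)
  sh <- simulate_taxon_hits(sa, seed = 19)
  v <- assign_taxa(sh$hits, sh$taxonomy,
                   contig_ids = contig_ids(sa$assembly))
  expect_identical(
    v$assigned_name[match(sh$manifest$contig_id, v$contig_id)],
    sh$manifest$expected_assignment)
  # no-hit count equals the planted fraction of host contigs
  n_host <- sum(!sa$manifest$is_contaminant)
  expect_equal(sum(v$assigned_name == "no-hit"), round(0.181 * n_host))
})

test_that("the comparison table reports the simulated genomes faithfully", {
  sa <- simulate_assembly(n_contigs = 12, seed = 23)
  ann <- simulate_annotation(sa, seed = 24)
  s <- list(
    genomeA = list(assembly = summarize_assembly(sa$assembly),
                   annotation = summarize_annotation(ann$annotation,
                                                     sa$assembly)),
    genomeB = list(assembly = summarize_assembly(sa$assembly)))
  tab <- comparison_table(s)
  expect_equal(ncol(tab), 3)
  expect_equal(tab$genomeA[tab$parameter == "Number of contigs"], 12)
  expect_equal(tab$genomeA[tab$parameter == "Number of gene models"],
               nrow(ann$manifest))
  expect_equal(tab$genomeA[tab$parameter == "Length (Mb)"],
               round(sum(sa$manifest$length) / 1e6, 3))
  expect_true(is.na(tab$genomeB[tab$parameter ==
                                  "Average number of exons per gene"]))
})
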