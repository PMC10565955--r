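# Readers and writers for FASTA, GFF3 and the TSV dialects.

test_that("FASTA reading preserves ids, order, case and lengths", {
  f <- write_tmp(c(">a desc", "acgtNN", ">b", "GG"), ".fa")
  asm <- read_fasta(f)
  expect_identical(contig_ids(asm), c("a", "b"))
  expect_identical(unname(contig_lengths(asm)), c(6L, 2L))
  expect_identical(as.character(asm$seqs[["a"]]), "acgtNN")

  f1 <- write_tmp(c(">c1", "ACGT"), ".fa")
  expect_identical(unname(contig_lengths(read_fasta(f1))), 4L)
})

test_that("FASTA rejects duplicate ids and empty records", {
  f <- write_tmp(c(">a", "ACGT", ">a", "GG"), ".fa")
  expect_error(read_fasta(f), "a")
  expect_error(assembly(c(a = "ACGT", a = "GG")), "duplicate")
  expect_error(assembly(c(a = "")), "empty")
  expect_error(assembly(c(a = "ACGT", b = "AXGT")), "non-IUPAC")
})

test_that("FASTA round trip is byte-identical at fixed wrap width", {
  set.seed(42)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "c", "g", "T", "N", "n"), sample(50:301, 1),
                 replace = TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("ctg", 1:5)
  asm <- assembly(seqs)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(asm, f1, width = 60)
  write_fasta(read_fasta(f1), f2, width = 60)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(as.character(read_fasta(f2)$seqs)), unname(seqs))
})

gff3_lines_basic <- c(
  "##gff-version 3",
  "c1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
  "c1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1",
  "c1\tsrc\texon\t1\t100\t.\t+\t.\tID=e1;Parent=t1",
  "c1\tsrc\texon\t201\t300\t.\t+\t.\tID=e2;Parent=t1")

test_that("GFF3 reader builds gene/transcript/exon hierarchy", {
  ann <- read_gff3(write_tmp(gff3_lines_basic, ".gff3"))
  expect_equal(nrow(ann$genes), 1)
  expect_equal(nrow(ann$transcripts), 1)
  expect_equal(nrow(ann$exons), 2)
  rex <- representative_exons(ann)
  expect_equal(sum(rex$end - rex$start + 1), 200)

  one <- read_gff3(write_tmp(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "c1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
    "c1\tsrc\texon\t1\t100\t.\t+\t.\tID=e1;Parent=t1"), ".gff3"))
  expect_equal(nrow(one$genes), 1)
  e <- representative_exons(one)
  expect_equal(e$end - e$start + 1, 100)
})

test_that("GFF3 reader is insensitive to feature order", {
  shuffled <- c("##gff-version 3", gff3_lines_basic[c(5, 3, 4, 2)])
  a <- read_gff3(write_tmp(gff3_lines_basic, ".gff3"))
  b <- read_gff3(write_tmp(shuffled, ".gff3"))
  expect_identical(representative_exons(a), representative_exons(b))
})

test_that("GFF3 reader skips orphan exons with a warning record", {
  lines <- c(gff3_lines_basic,
             "c1\tsrc\texon\t400\t500\t.\t+\t.\tID=e3;Parent=missing_tx")
  ann <- read_gff3(write_tmp(lines, ".gff3"))
  expect_equal(nrow(ann$exons), 2)
  expect_match(ann$warnings, "missing_tx", all = FALSE)
})

test_that("GFF3 reader errors hard on end < start and missing directive", {
  bad <- c("##gff-version 3",
           "c1\tsrc\tgene\t100\t1\t.\t+\t.\tID=g1")
  expect_error(read_gff3(write_tmp(bad, ".gff3")), "end < start")
  expect_error(read_gff3(write_tmp(gff3_lines_basic[-1], ".gff3")),
               "gff-version")
})

test_that("transcripts with only CDS children get exons synthesized", {
  lines <- c("##gff-version 3",
             "c1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
             "c1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1",
             "c1\tsrc\tCDS\t10\t99\t.\t+\t0\tID=cds1;Parent=t1",
             "c1\tsrc\tCDS\t200\t289\t.\t+\t0\tID=cds2;Parent=t1")
  ann <- read_gff3(write_tmp(lines, ".gff3"))
  rex <- representative_exons(ann)
  expect_equal(nrow(rex), 2)
  expect_equal(rex$start, c(10, 200))
})

test_that("representative transcript is longest-CDS, ties lexicographic", {
  ann <- annotation_set(
    genes = data.frame(gene_id = c("g1", "g2"), contig_id = "c1",
                       strand = "+"),
    transcripts = data.frame(transcript_id = c("t1a", "t1b", "t2b", "t2a"),
                             gene_id = c("g1", "g1", "g2", "g2")),
    exons = data.frame(transcript_id = c("t1a", "t1b", "t2b", "t2a"),
                       start = c(1, 1, 1, 1), end = c(100, 400, 50, 50)),
    cds = data.frame(transcript_id = c("t1a", "t1b", "t2b", "t2a"),
                     start = c(1, 1, 1, 1), end = c(99, 300, 50, 50)))
  expect_identical(ann$genes$representative, c("t1b", "t2a"))
})

test_that("orthogroup TSV parsing counts comma-separated tokens", {
  f <- write_tmp(c("Orthogroup\ts1\ts2\ts3",
                   "OG1\tg1, g2\t\t",
                   "OG2\t \tg3\tg4,g5,g6"), ".tsv")
  tab <- read_orthogroups_tsv(f)
  expect_identical(unname(tab["OG1", ]), c(2L, 0L, 0L))
  expect_identical(unname(tab["OG2", ]), c(0L, 1L, 3L))

  empty <- read_orthogroups_tsv(write_tmp("Orthogroup\ts1\ts2", ".tsv"))
  expect_equal(nrow(empty), 0)

  dup <- write_tmp(c("Orthogroup\ts1", "OG1\tg1", "OG1\tg2"), ".tsv")
  expect_error(read_orthogroups_tsv(dup), "duplicate")
})

test_that("orthogroup TSV round trip recovers counts exactly", {
  so <- simulate_orthogroups(
    design = c("Cnidaria" = 8, "Acoelomorpha+Deuterostomia" = 5,
               "Cnidaria+Acoelomorpha+Deuterostomia+Protostomia" = 7),
    seed = 4)
  f <- tempfile(fileext = ".tsv")
  write_orthogroups_tsv(so$table, f)
  back <- read_orthogroups_tsv(f)
  expect_identical(dim(back), dim(so$table))
  expect_true(all(back[rownames(so$table), colnames(so$table)] == so$table))
})

test_that("hit table parsing validates numerics and handles empty input", {
  f <- write_tmp("c1\tp1\t98.5\t100\t1\t0\t1\t300\t1\t100\t1e-50\t200.1\t6040",
                 ".tsv")
  h <- read_hits_tsv(f)
  expect_equal(nrow(h), 1)
  expect_equal(h$bitscore, 200.1)
  expect_equal(h$subject_taxid, 6040L)

  ef <- tempfile(); file.create(ef)
  expect_equal(nrow(read_hits_tsv(ef)), 0)

  bad <- write_tmp(c(
    "c1\tp1\t98.5\t100\t1\t0\t1\t300\t1\t100\t1e-50\t200.1\t6040",
    "c2\tp2\t98.5\t100\t1\t0\t1\t300\t1\t100\t1e-50\tNOTANUMBER\t6040"),
    ".tsv")
  expect_error(read_hits_tsv(bad), "line 2.*bitscore")
})

test_that("generated hit tables round trip with matching field sums", {
  sa <- simulate_assembly(n_contigs = 120, length_meanlog = log(5000),
                          seed = 8)
  sh <- simulate_taxon_hits(sa, seed = 8)
  f <- tempfile(fileext = ".tsv")
  write_hits_tsv(sh$hits, f)
  back <- read_hits_tsv(f)
  expect_equal(nrow(back), nrow(sh$hits))
  expect_equal(sum(back$bitscore), sum(sh$hits$bitscore))
  expect_equal(sum(back$subject_taxid), sum(sh$hits$subject_taxid))
})

test_that("clade and taxonomy TSVs round trip", {
  so <- simulate_orthogroups(design = c("Cnidaria" = 3), seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_clades_tsv(so$clades, f)
  back <- read_clades_tsv(f)
  expect_identical(as.character(back[names(so$clades)]),
                   as.character(so$clades))
  expect_identical(attr(back, "subclade")[["nem1"]], "Nemertodermatida")

  tf <- tempfile(fileext = ".tsv")
  write_taxonomy_tsv(default_taxonomy(), tf)
  tax <- read_taxonomy_tsv(tf)
  expect_identical(tax$phylum, default_taxonomy()$phylum)
})
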