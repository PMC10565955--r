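# Presence matrix, architecture extraction, fragment filter, test cascade.

test_that("presence calls apply both e-value and coverage thresholds", {
  ph <- simulate_panel_hits(seed = 61)
  pm <- build_presence_matrix(ph$hit_tables, query_lengths = ph$query_lengths)
  des <- ph$manifest
  calls <- mapply(function(f, s) pm[f, s], des$family, des$species)
  expect_identical(unname(calls == "annotated"), des$present)

  # species in the universe without a hit table is no-data, not absent
  pm2 <- build_presence_matrix(ph$hit_tables,
                               query_lengths = ph$query_lengths,
                               species = c(names(ph$hit_tables), "ghost"))
  expect_true(all(pm2[, "ghost"] == "no-data"))

  # genbank support upgrades non-annotated cells only
  gb <- data.frame(family = c("Osr", "ZO1"), species = c("aco1", "deu1"))
  pm3 <- build_presence_matrix(ph$hit_tables,
                               query_lengths = ph$query_lengths,
                               genbank_support = gb)
  expect_equal(pm3["Osr", "aco1"], "genbank")
  expect_equal(pm3["ZO1", "deu1"], "annotated")
})

test_that("architecture metrics come from representative exons and proteome", {
  ann <- annotation_set(
    genes = data.frame(gene_id = c("gA", "gB"), contig_id = "c1",
                       strand = "+"),
    transcripts = data.frame(transcript_id = c("gA.t", "gB.t"),
                             gene_id = c("gA", "gB")),
    exons = rbind(
      data.frame(transcript_id = "gA.t", start = c(1, 101),
                 end = c(90, 190)),
      data.frame(transcript_id = "gB.t", start = 1, end = 300)))
  prot <- c(gA.t = strrep("M", 59), gB.t = strrep("M", 99))
  pm <- data.frame(gene_id = c("gA", "gB"), family = c("Eya", "Osr"),
                   species = "sp1", clade = "Acoelomorpha")
  rec <- extract_architecture(ann, prot, pm)
  expect_equal(rec$n_exons, c(2L, 1L))
  expect_equal(rec$mean_exon_length, c(90, 300))
  expect_equal(rec$protein_length, c(59L, 99L))

  # missing protein keeps exon metrics with NA length
  rec2 <- extract_architecture(ann, prot["gA.t"], pm)
  expect_true(is.na(rec2$protein_length[2]))
  expect_equal(rec2$n_exons[2], 1L)
})

test_that("fragment filter uses the pooled family mean, single pass", {
  rec <- data.frame(family = "Eya", protein_length = c(100, 100, 100, 40))
  ff <- fragment_filter(rec)
  expect_equal(unname(ff$thresholds["Eya"]), 42.5)
  expect_equal(ff$removed$protein_length, 40)

  same <- fragment_filter(data.frame(family = "Eya",
                                     protein_length = rep(77, 5)))
  expect_equal(nrow(same$removed), 0)

  # brute-force equivalence on random inputs, multiple families pooled
  set.seed(71)
  for (rep in 1:10) {
    rec <- data.frame(
      family = sample(c("A", "B", "C"), 60, replace = TRUE),
      protein_length = round(stats::runif(60, 20, 1000)))
    ff <- fragment_filter(rec)
    expect_identical(ff$removed$protein_length,
                     rec$protein_length[oracle_fragment_filter(rec)])
  }
})

test_that("the cascade picks ANOVA on clean normal data and isolates a shifted clade", {
  set.seed(81)
  rec <- normal_records("ZO1", c("Cnidaria", "Acoelomorpha",
                                 "Deuterostomia", "Protostomia"),
                        n = 20, means = c(0, 10, 0, 0), sd = 1)
  out <- compare_clades(rec, "ZO1", "protein_length")
  expect_equal(out$omnibus, "ANOVA")
  expect_true(out$normality_pass && out$homoscedasticity_pass)
  expect_lt(out$omnibus_p, 0.05)
  solo <- vapply(out$brackets, function(b) identical(b, "Acoelomorpha"),
                 logical(1))
  expect_true(any(solo))
  other <- setdiff(c("Cnidaria", "Deuterostomia", "Protostomia"), NULL)
  expect_true(any(vapply(out$brackets, function(b) setequal(b, other),
                         logical(1))))
})

test_that("identical groups give a non-significant omnibus and one bracket", {
  rec <- normal_records("Eya", c("Deuterostomia", "Protostomia"), n = 3,
                        means = c(0, 0))
  rec$protein_length <- rep(c(1, 2, 3), 2)
  out <- compare_clades(rec, "Eya", "protein_length")
  expect_gt(out$omnibus_p, 0.05)
  expect_length(out$brackets, 1)
  expect_setequal(out$brackets[[1]], c("Deuterostomia", "Protostomia"))
  expect_null(out$pairwise)
})

test_that("constant data is flagged degenerate, not significant", {
  rec <- normal_records("Eya", c("Deuterostomia", "Protostomia"), n = 4,
                        means = c(0, 0))
  rec$protein_length <- rep(c(5, 9), each = 4)
  out <- compare_clades(rec, "Eya", "protein_length")
  expect_true(out$degenerate)
  expect_equal(out$omnibus_p, 1)
})

test_that("groups below n = 3 force the nonparametric branch", {
  set.seed(82)
  rec <- normal_records("Sall", c("Deuterostomia", "Protostomia"), n = 2,
                        means = c(0, 0))
  out <- compare_clades(rec, "Sall", "protein_length")
  expect_false(out$normality_pass)
  expect_equal(out$omnibus, "Kruskal-Wallis")

  expect_error(compare_clades(rec[rec$clade == "Protostomia", ], "Sall",
                              "protein_length"), "fewer than 2 clades")
})

test_that("Kruskal-Wallis branch is invariant to monotone transformation", {
  set.seed(83)
  rec <- rbind(
    normal_records("Lhx1/5", c("Acoelomorpha", "Protostomia"), n = 8,
                   means = c(0, 3), sd = 1),
    normal_records("Lhx1/5", "Deuterostomia", n = 2, means = 1, sd = 1))
  rec$protein_length <- exp(rec$protein_length)
  out1 <- compare_clades(rec, "Lhx1/5", "protein_length")
  rec2 <- rec
  rec2$protein_length <- log(rec$protein_length)  # monotone transform
  out2 <- compare_clades(rec2, "Lhx1/5", "protein_length")
  # the n = 2 group forces the nonparametric branch in both runs
  expect_equal(out1$omnibus, "Kruskal-Wallis")
  expect_equal(out2$omnibus, "Kruskal-Wallis")
  expect_equal(out1$omnibus_p, out2$omnibus_p)
})

test_that("Dunn statistics match the longhand oracle and its symmetries", {
  set.seed(84)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    n <- sample(4:9, k, replace = TRUE)
    groups <- rep(letters[1:k], n)
    values <- round(stats::rnorm(sum(n)), sample(0:1, 1))  # forces ties
    d <- dunn_test(values, groups, p_adjust = "none")
    for (i in seq_len(nrow(d))) {
      expect_equal(d$z[i],
                   oracle_dunn_z(values, groups, d$group1[i], d$group2[i]))
    }
    # antisymmetry under group swap
    swapped <- ifelse(groups == "a", "b", ifelse(groups == "b", "a", groups))
    d2 <- dunn_test(values, swapped, p_adjust = "none")
    z_ab <- d$z[d$group1 == "a" & d$group2 == "b"]
    z2_ab <- d2$z[d2$group1 == "a" & d2$group2 == "b"]
    expect_equal(z_ab, -z2_ab)
  }

  # without ties the tie-correction term vanishes
  values <- c(1, 2, 3, 4, 5, 6, 7, 8)
  groups <- rep(c("a", "b"), each = 4)
  d <- dunn_test(values, groups, p_adjust = "none")
  N <- 8
  se_noties <- sqrt(N * (N + 1) / 12 * (1 / 4 + 1 / 4))
  expect_equal(d$z, (mean(rank(values)[1:4]) - mean(rank(values)[5:8])) /
                 se_noties)
})

test_that("adjusted p-values dominate raw ones and cap at 1", {
  set.seed(85)
  rec <- normal_records("POU3", c("Cnidaria", "Acoelomorpha",
                                  "Deuterostomia", "Protostomia"),
                        n = 10, means = c(0, 4, 0, 0), sd = 1)
  rec$protein_length <- exp(rec$protein_length / 4)
  out <- compare_clades(rec, "POU3", "protein_length")
  if (!is.null(out$pairwise)) {
    expect_true(all(out$pairwise$p_adj >= out$pairwise$p_raw - 1e-12))
    expect_true(all(out$pairwise$p_adj <= 1))
  }
  d <- dunn_test(rec$protein_length, rec$clade, p_adjust = "bonferroni")
  expect_true(all(d$p_adj >= d$p_raw - 1e-12))
  expect_true(all(d$p_adj <= 1))
})

test_that("panel comparison runs per family x metric and skips single-clade families", {
  set.seed(86)
  rec <- rbind(
    normal_records("Osr", c("Deuterostomia", "Protostomia"), n = 6,
                   means = c(0, 0)),
    normal_records("Eya", c("Acoelomorpha"), n = 6, means = 0))
  pc <- run_panel_comparison(rec)
  expect_setequal(unique(pc$summary$family), "Osr")
  expect_equal(nrow(pc$summary), 3)
  # Osr tested over exactly its two clades
  expect_setequal(names(pc$outcomes[["Osr:protein_length"]]$groups),
                  c("Deuterostomia", "Protostomia"))
  expect_equal(unique(pc$skipped$family), "Eya")

  empty <- run_panel_comparison(rec[0, ])
  expect_length(empty$outcomes, 0)
  expect_equal(nrow(empty$summary), 0)
})

test_that("planted 10-sigma effects are all detected; false alarms stay near alpha", {
  eff <- data.frame(
    family = c("Kirrel", "ZO1", "Eya", "Sall"),
    metric = c("protein_length", "n_exons", "mean_exon_length",
               "mean_exon_length"),
    clade = c("Acoelomorpha", "Acoelomorpha", "Acoelomorpha",
              "Deuterostomia"),
    shift = c(600, 12, 200, 200))
  sr <- simulate_architecture_records(n_per_clade = 15, effects = eff,
                                      seed = 87)
  pc <- run_panel_comparison(sr$records)
  sig <- paste(pc$summary$family, pc$summary$metric)[pc$summary$significant]
  planted <- paste(eff$family, eff$metric)
  expect_true(all(planted %in% sig))   # power ~ 1 at 10-sigma shifts
  # 23 null combinations at alpha 0.05: a handful of false alarms is the
  # method behaving as specified, more would indicate a defect
  expect_lte(length(setdiff(sig, planted)), 3)
  # and each planted effect isolates the shifted clade in its own bracket
  for (i in seq_len(nrow(eff))) {
    o <- pc$outcomes[[paste(eff$family[i], eff$metric[i], sep = ":")]]
    expect_true(any(vapply(o$brackets, function(b)
      identical(b, eff$clade[i]), logical(1))))
  }
})
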