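# Independent brute-force oracles and tiny fixture builders. Oracles are
# written from the definitions, not by calling package internals.

oracle_n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  acc <- 0
  for (l in lens) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

# clade partition by explicit set construction, one orthogroup at a time
oracle_partition <- function(counts, clades) {
  out <- list()
  for (og in rownames(counts)) {
    present <- character()
    for (sp in colnames(counts)) {
      if (counts[og, sp] >= 1) present <- union(present, clades[[sp]])
    }
    out[[og]] <- sort(present)
  }
  out
}

oracle_shared_sets <- function(part_list, outgroup = "Cnidaria") {
  met <- bil <- character()
  for (og in names(part_list)) {
    cl <- part_list[[og]]
    if (outgroup %in% cl && length(cl) >= 2) met <- c(met, og)
    if (!(outgroup %in% cl) && length(cl) >= 2) bil <- c(bil, og)
  }
  list(metazoan = met, bilaterian = bil)
}

oracle_fragment_filter <- function(records) {
  removed <- logical(nrow(records))
  for (f in unique(records$family)) {
    idx <- which(records$family == f)
    thr <- 0.5 * mean(records$protein_length[idx])
    removed[idx] <- records$protein_length[idx] < thr
  }
  removed
}

# Dunn z statistics written out longhand from the joint-rank definition
oracle_dunn_z <- function(values, groups, g1, g2) {
  N <- length(values)
  r <- rank(values)
  tie_sizes <- as.vector(table(values))
  T_corr <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  m1 <- mean(r[groups == g1]); m2 <- mean(r[groups == g2])
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  (m1 - m2) / sqrt((N * (N + 1) / 12 - T_corr) * (1 / n1 + 1 / n2))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# minimal random orthogroup count matrix
random_og_table <- function(n_og, species, p_present = 0.3) {
  m <- matrix(stats::rbinom(n_og * length(species), 2, p_present),
              nrow = n_og,
              dimnames = list(sprintf("OG%04d", seq_len(n_og)), species))
  m[rowSums(m) == 0, sample(length(species), 1)] <- 1L
  orthogroup_table(m)
}

four_clade_map <- function() {
  c(cni1 = "Cnidaria", cni2 = "Cnidaria",
    aco1 = "Acoelomorpha", nem1 = "Acoelomorpha",
    deu1 = "Deuterostomia", deu2 = "Deuterostomia",
    pro1 = "Protostomia", pro2 = "Protostomia")
}

# inline architecture records with raw (unrounded) normal metrics
normal_records <- function(family, clades, n, means, sd = 1) {
  do.call(rbind, lapply(seq_along(clades), function(i) {
    data.frame(species = paste0(clades[i], "_sp", seq_len(n)),
               clade = clades[i], family = family,
               gene_id = paste0(family, clades[i], seq_len(n)),
               protein_length = stats::rnorm(n, means[i], sd),
               n_exons = stats::rnorm(n, means[i], sd),
               mean_exon_length = stats::rnorm(n, means[i], sd),
               stringsAsFactors = FALSE)
  }))
}
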