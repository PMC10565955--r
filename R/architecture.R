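# Excretory-gene panel: presence/absence matrix, gene-architecture metric
# extraction, fragment filtering, and the clade-comparison test cascade.
#
# The cascade per gene family and metric: Shapiro-Wilk normality per clade
# group and a Bartlett homoscedasticity test gate the choice of omnibus
# test; ANOVA (both gates pass) or Kruskal-Wallis otherwise. When the
# omnibus is significant at alpha, pairwise post-hoc tests follow: pooled
# two-sample t tests with Bonferroni multiplication on the ANOVA branch,
# Dunn's joint-rank z tests (with tie correction) on the Kruskal-Wallis
# branch. Clades are finally grouped into brackets (maximal sets with no
# significant mutual differences), the compact display used under the
# boxplots of cross-clade comparisons.

#' The ultrafiltration excretory-system gene panel
#'
#' Nine genes involved in building or patterning nephridia-type
#' ultrafiltration organs: the structural slit-diaphragm/junction proteins
#' Nephrin, Kirrel and ZO1, and six developmental transcription factors.
#'
#' @return data.frame with columns `family` and `role`.
#' @export
excretory_panel <- function() {
  data.frame(
    family = c("Nephrin", "Kirrel", "ZO1",
               "Eya", "Lhx1/5", "Osr", "POU3", "Sall", "Six1"),
    role = c(rep("structural", 3), rep("transcription factor", 6)),
    stringsAsFactors = FALSE)
}

#' Build a gene-panel presence/absence matrix
#'
#' A family is called `annotated` in a species iff at least one hit of that
#' family's query passes both the e-value and query-coverage thresholds;
#' otherwise `absent`. Species listed in `species` but lacking a hit table
#' are `no-data` (absence can only be called against a searched proteome).
#' An optional override marks externally supported presences (e.g. from a
#' sequence archive) as `genbank` wherever the local call is not
#' `annotated`.
#'
#' @param hit_tables Named list, species -> hit table ([read_hits_tsv()]
#'   format) of panel queries vs that species' proteome; `query_id` must be
#'   the family name.
#' @param panel Panel data.frame (default [excretory_panel()]).
#' @param query_lengths Named numeric, family -> query length (aa), used to
#'   compute query coverage as `(qend - qstart + 1) / length`.
#' @param max_evalue Maximum e-value for a passing hit (default `1e-5`).
#' @param min_query_cov Minimum query coverage fraction (default `0.5`).
#' @param species Optional full species universe (default:
#'   `names(hit_tables)`).
#' @param genbank_support Optional data.frame with columns `family`,
#'   `species` of externally supported presences.
#' @return Character matrix of class `"presence_matrix"`, families x
#'   species, entries in `{"annotated", "genbank", "absent", "no-data"}`.
#' @export
build_presence_matrix <- function(hit_tables, panel = excretory_panel(),
                                  query_lengths, max_evalue = 1e-5,
                                  min_query_cov = 0.5, species = NULL,
                                  genbank_support = NULL) {
  if (is.null(species)) species <- names(hit_tables)
  fams <- panel$family
  miss_len <- setdiff(fams, names(query_lengths))
  if (length(miss_len) > 0) stop("missing query length(s) for: ",
                                 paste(miss_len, collapse = ", "))
  m <- matrix("no-data", nrow = length(fams), ncol = length(species),
              dimnames = list(fams, species))
  for (sp in intersect(species, names(hit_tables))) {
    h <- hit_tables[[sp]]
    cov <- (h$qend - h$qstart + 1) / query_lengths[h$query_id]
    pass <- h$evalue <= max_evalue & cov >= min_query_cov
    found <- unique(h$query_id[pass])
    m[, sp] <- ifelse(fams %in% found, "annotated", "absent")
  }
  if (!is.null(genbank_support)) {
    for (i in seq_len(nrow(genbank_support))) {
      f <- genbank_support$family[i]; sp <- genbank_support$species[i]
      if (f %in% fams && sp %in% species && m[f, sp] != "annotated") {
        m[f, sp] <- "genbank"
      }
    }
  }
  class(m) <- c("presence_matrix", "matrix", "array")
  m
}

#' Aggregate a presence matrix to clades
#'
#' @param m A `"presence_matrix"`.
#' @param clades Named character vector species -> clade.
#' @return Character matrix families x clades: `annotated` if any species
#'   of the clade is annotated, else `genbank` if any is, else `absent`
#'   (`no-data` when no species of the clade was searched).
#' @export
collapse_presence_by_clade <- function(m, clades) {
  stopifnot(inherits(m, "presence_matrix"))
  labs <- sort(unique(unname(clades[colnames(m)])))
  out <- vapply(labs, function(cl) {
    sub <- m[, colnames(m)[clades[colnames(m)] == cl], drop = FALSE]
    apply(sub, 1, function(states) {
      if (any(states == "annotated")) "annotated"
      else if (any(states == "genbank")) "genbank"
      else if (any(states == "absent")) "absent"
      else "no-data"
    })
  }, character(nrow(m)))
  matrix(out, nrow = nrow(m), dimnames = list(rownames(m), labs))
}

#' Extract gene-architecture metrics for panel genes
#'
#' For each panel gene copy: protein length (aa) from the proteome, and
#' exon count and mean exon length (bp) from the representative
#' transcript's exon intervals. Proteins are resolved by representative
#' transcript id first, then by gene id. Genes without exon features are
#' skipped with a warning; genes without a resolvable protein keep their
#' exon metrics and get `NA` protein length.
#'
#' @param annotation An [annotation_set()] containing the panel genes.
#' @param proteome Named character vector or `XStringSet` of protein
#'   sequences.
#' @param panel_map data.frame with columns `gene_id`, `family`, `species`,
#'   `clade` identifying each annotated panel gene copy.
#' @return data.frame of architecture records: `species`, `clade`,
#'   `family`, `gene_id`, `protein_length`, `n_exons`, `mean_exon_length`.
#' @export
extract_architecture <- function(annotation, proteome, panel_map) {
  stopifnot(inherits(annotation, "annotation_set"))
  if (methods::is(proteome, "XStringSet")) {
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  }
  missing <- setdiff(panel_map$gene_id, annotation$genes$gene_id)
  if (length(missing) > 0) {
    stop("panel gene(s) not in annotation: ", paste(missing, collapse = ", "))
  }
  rex <- representative_exons(annotation)
  gidx <- match(panel_map$gene_id, annotation$genes$gene_id)
  rep_tx <- annotation$genes$representative[gidx]
  records <- lapply(seq_len(nrow(panel_map)), function(i) {
    g <- panel_map$gene_id[i]
    e <- rex[rex$gene_id == g, , drop = FALSE]
    if (nrow(e) == 0) {
      warning("gene ", g, " has no exon features; skipped")
      return(NULL)
    }
    exlen <- e$end - e$start + 1L
    prot <- NULL
    if (!is.na(rep_tx[i]) && rep_tx[i] %in% names(proteome)) {
      prot <- proteome[[rep_tx[i]]]
    } else if (g %in% names(proteome)) {
      prot <- proteome[[g]]
    }
    data.frame(species = panel_map$species[i], clade = panel_map$clade[i],
               family = panel_map$family[i], gene_id = g,
               protein_length = if (is.null(prot)) NA_integer_
                                else nchar(prot),
               n_exons = nrow(e), mean_exon_length = mean(exlen),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, records)
  if (is.null(out)) {
    out <- data.frame(species = character(), clade = character(),
                      family = character(), gene_id = character(),
                      protein_length = integer(), n_exons = integer(),
                      mean_exon_length = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Filter out fragmented protein copies
#'
#' Removes records whose protein length falls below half the arithmetic
#' mean protein length of their gene family, the mean being taken over ALL
#' records of the family (all clades pooled) and computed once before any
#' removal (single pass, not iterated). Records without a protein length
#' are never removed.
#'
#' @param records Architecture records ([extract_architecture()] output).
#' @return List with `kept`, `removed` (data.frames) and `thresholds`
#'   (named numeric, family -> length cutoff in aa).
#' @export
fragment_filter <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("family", "protein_length") %in% names(records)))
  fams <- unique(records$family)
  thresholds <- vapply(fams, function(f) {
    len <- records$protein_length[records$family == f]
    0.5 * mean(len, na.rm = TRUE)
  }, numeric(1))
  drop <- !is.na(records$protein_length) &
    records$protein_length < thresholds[records$family]
  list(kept = records[!drop, , drop = FALSE],
       removed = records[drop, , drop = FALSE],
       thresholds = thresholds)
}

#' Dunn's post-hoc test on joint ranks
#'
#' Pairwise z tests on group mean ranks following a Kruskal-Wallis omnibus
#' test, with the standard correction for tied ranks:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` where
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups of size `t`.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector of group labels, same length.
#' @param p_adjust Multiplicity adjustment: `"bonferroni"` (default),
#'   `"holm"` or `"none"`.
#' @return data.frame with columns `group1`, `group2`, `z`, `p_raw`,
#'   `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  p_adjust <- match.arg(p_adjust, c("bonferroni", "holm", "none"))
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  labs <- names(rbar)
  pairs <- utils::combn(labs, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[p[1]] + 1 / n[p[2]]))
    (rbar[p[1]] - rbar[p[2]]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (p_adjust == "none") p_raw else
    stats::p.adjust(p_raw, method = p_adjust)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z),
             p_raw = as.numeric(p_raw), p_adj = as.numeric(p_adj),
             stringsAsFactors = FALSE)
}

# Maximal sets of groups with no significant mutual difference, ordered by
# group median. `nonsig` is a symmetric logical matrix over group labels.
.grouping_brackets <- function(labs_ordered, nonsig) {
  k <- length(labs_ordered)
  if (k == 1) return(list(labs_ordered))
  subsets <- list()
  for (size in k:1) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      members <- labs_ordered[idx]
      ok <- all(nonsig[members, members])
      if (ok) {
        covered <- any(vapply(subsets, function(s) all(members %in% s),
                              logical(1)))
        if (!covered) subsets[[length(subsets) + 1]] <- members
      }
    }
  }
  subsets
}

#' Compare a metric across clades for one gene family
#'
#' Runs the gated test cascade on one family x metric combination: per-clade
#' Shapiro-Wilk (every group with n >= 3 must pass at `alpha`; a group with
#' n < 3 forces non-normality) and Bartlett's test choose between a one-way
#' ANOVA (both pass) and a Kruskal-Wallis test. If the omnibus p-value is
#' below `alpha`, pairwise comparisons follow: pooled-variance t tests with
#' Bonferroni multiplication (ANOVA branch) or [dunn_test()] (Kruskal-Wallis
#' branch). Clades with fewer than 2 records are dropped; fewer than 2
#' usable clades is an error. If every clade's values are constant the
#' outcome is flagged degenerate and reported non-significant.
#'
#' @param records Architecture records.
#' @param family Gene family to test.
#' @param metric One of `"protein_length"`, `"n_exons"`,
#'   `"mean_exon_length"`.
#' @param alpha Significance threshold (default `0.05`).
#' @param p_adjust Post-hoc adjustment for the Dunn branch (default
#'   `"bonferroni"`).
#' @return List of class `"test_outcome"`: `family`, `metric`, `groups`
#'   (per-clade n), `normality_pass`, `homoscedasticity_pass`, `omnibus`
#'   (`"ANOVA"` or `"Kruskal-Wallis"`), `omnibus_p`, `pairwise` (data.frame
#'   or `NULL`), `significant_pairs`, `brackets` (list of clade sets) and
#'   `degenerate`.
#' @export
compare_clades <- function(records, family, metric, alpha = 0.05,
                           p_adjust = "bonferroni") {
  stopifnot(metric %in% names(records))
  sub <- records[records$family == family & !is.na(records[[metric]]), ,
                 drop = FALSE]
  n_by <- table(sub$clade)
  usable <- names(n_by)[n_by >= 2]
  if (length(usable) < 2) {
    stop("fewer than 2 clades with >= 2 records for ", family, " / ", metric)
  }
  sub <- sub[sub$clade %in% usable, , drop = FALSE]
  x <- sub[[metric]]
  g <- factor(sub$clade)

  grp_values <- split(x, g)
  degenerate <- all(vapply(grp_values, function(v) stats::var(v) == 0,
                           logical(1)))
  medians <- sort(vapply(grp_values, stats::median, numeric(1)))
  labs_ordered <- names(medians)

  if (degenerate) {
    normality <- FALSE; homosced <- FALSE
    omnibus <- "Kruskal-Wallis"; omnibus_p <- 1
  } else {
    normality <- all(vapply(grp_values, function(v) {
      if (length(v) < 3) return(FALSE)
      if (stats::var(v) == 0) return(FALSE)   # shapiro undefined; not normal
      stats::shapiro.test(v)$p.value > alpha
    }, logical(1)))
    homosced <- if (any(vapply(grp_values, stats::var, numeric(1)) == 0))
      FALSE else stats::bartlett.test(x, g)$p.value > alpha
    if (normality && homosced) {
      omnibus <- "ANOVA"
      omnibus_p <- stats::oneway.test(x ~ g, var.equal = TRUE)$p.value
    } else {
      omnibus <- "Kruskal-Wallis"
      omnibus_p <- stats::kruskal.test(x, g)$p.value
    }
  }

  pairwise <- NULL
  nonsig <- matrix(TRUE, length(labs_ordered), length(labs_ordered),
                   dimnames = list(labs_ordered, labs_ordered))
  if (!degenerate && omnibus_p < alpha) {
    if (omnibus == "ANOVA") {
      pr <- utils::combn(levels(g), 2)
      n_pairs <- ncol(pr)
      p_raw <- apply(pr, 2, function(p) {
        stats::t.test(grp_values[[p[1]]], grp_values[[p[2]]],
                      var.equal = TRUE)$p.value
      })
      pairwise <- data.frame(group1 = pr[1, ], group2 = pr[2, ],
                             p_raw = p_raw,
                             p_adj = pmin(1, p_raw * n_pairs),
                             stringsAsFactors = FALSE)
    } else {
      pairwise <- dunn_test(x, as.character(g), p_adjust = p_adjust)
    }
    for (i in seq_len(nrow(pairwise))) {
      if (pairwise$p_adj[i] < alpha) {
        nonsig[pairwise$group1[i], pairwise$group2[i]] <- FALSE
        nonsig[pairwise$group2[i], pairwise$group1[i]] <- FALSE
      }
    }
  }
  sig_pairs <- if (is.null(pairwise)) character() else
    paste(pairwise$group1, pairwise$group2, sep = "|")[pairwise$p_adj < alpha]

  structure(list(family = family, metric = metric,
                 groups = stats::setNames(as.integer(table(g)),
                                          names(table(g))),
                 normality_pass = normality,
                 homoscedasticity_pass = homosced,
                 omnibus = omnibus, omnibus_p = omnibus_p,
                 pairwise = pairwise, significant_pairs = sig_pairs,
                 brackets = .grouping_brackets(labs_ordered, nonsig),
                 degenerate = degenerate),
            class = "test_outcome")
}

#' @export
print.test_outcome <- function(x, ...) {
  cat(sprintf("<test_outcome> %s / %s: %s p = %.4g; brackets: %s\n",
              x$family, x$metric, x$omnibus, x$omnibus_p,
              paste(vapply(x$brackets, paste, character(1), collapse = ","),
                    collapse = " | ")))
  invisible(x)
}

#' Run the full panel comparison
#'
#' Applies [compare_clades()] to every gene family present in `records`
#' crossed with the three architecture metrics. Family x metric
#' combinations with fewer than 2 clades of >= 2 records are skipped with
#' an explicit reason (e.g. a gene present in a single clade).
#'
#' @param records Architecture records (after [fragment_filter()]).
#' @param alpha Significance threshold (default `0.05`).
#' @param metrics Metrics to test.
#' @param p_adjust Post-hoc adjustment for the Dunn branch.
#' @return List of class `"panel_comparison"` with `outcomes` (list of
#'   `"test_outcome"`), `skipped` (data.frame `family`, `metric`, `reason`)
#'   and `summary` (one row per tested combination: omnibus, p,
#'   significance, bracket display).
#' @export
run_panel_comparison <- function(records, alpha = 0.05,
                                 metrics = c("protein_length", "n_exons",
                                             "mean_exon_length"),
                                 p_adjust = "bonferroni") {
  outcomes <- list()
  skipped <- data.frame(family = character(), metric = character(),
                        reason = character(), stringsAsFactors = FALSE)
  for (fam in unique(records$family)) {
    for (met in metrics) {
      sub <- records[records$family == fam & !is.na(records[[met]]), ,
                     drop = FALSE]
      usable <- names(which(table(sub$clade) >= 2))
      if (length(usable) < 2) {
        skipped <- rbind(skipped, data.frame(
          family = fam, metric = met,
          reason = sprintf("only %d clade(s) with >= 2 records",
                           length(usable)),
          stringsAsFactors = FALSE))
        next
      }
      outcomes[[paste(fam, met, sep = ":")]] <-
        compare_clades(records, fam, met, alpha = alpha, p_adjust = p_adjust)
    }
  }
  summary <- do.call(rbind, lapply(outcomes, function(o) {
    data.frame(family = o$family, metric = o$metric, omnibus = o$omnibus,
               omnibus_p = o$omnibus_p,
               significant = o$omnibus_p < alpha && !o$degenerate,
               n_significant_pairs = length(o$significant_pairs),
               brackets = paste(vapply(o$brackets, paste, character(1),
                                       collapse = ","), collapse = " | "),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary)) {
    summary <- data.frame(family = character(), metric = character(),
                          omnibus = character(), omnibus_p = numeric(),
                          significant = logical(),
                          n_significant_pairs = integer(),
                          brackets = character())
  }
  rownames(summary) <- NULL
  structure(list(outcomes = outcomes, skipped = skipped, summary = summary),
            class = "panel_comparison")
}
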