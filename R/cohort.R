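#' Summarize a cohort of variant events
#'
#' Descriptive statistics over a variant table: events per patient, per
#' gene and per chromosome, per-gene recurrence (fraction of patients
#' carrying at least one event in the gene) and zygosity counts. The
#' recurrence denominator is the number of patients in `patients` when
#' supplied, otherwise the number of distinct `patient_id`s observed.
#'
#' @param variants variant table.
#' @param patients optional patient metadata table (one row per patient)
#'   fixing the cohort size.
#' @return object of class `spex_cohort_summary`: list with
#'   `per_patient_counts`, `per_gene_events`, `per_chromosome_counts`,
#'   `recurrence`, `zygosity_counts`, `n_patients`.
#' @examples
#' s <- summarize_cohort(load_fixture("table2_snps"))
#' s$recurrence[["CTNNB1"]]
#' @export
summarize_cohort <- function(variants, patients = NULL) {
  variants <- as_variant_table(variants)
  if (!is.null(patients)) {
    stopifnot("patient_id" %in% names(patients))
    missing_meta <- setdiff(variants$patient_id, patients$patient_id)
    if (length(missing_meta)) {
      stop("variants reference unknown patient_id(s): ",
           paste(missing_meta, collapse = ", "), call. = FALSE)
    }
    n_patients <- length(unique(patients$patient_id))
  } else {
    n_patients <- length(unique(variants$patient_id))
  }
  per_patient <- table(variants$patient_id)
  per_gene <- table(variants$gene)
  per_chrom <- table(factor(variants$chromosome, levels = CHROMOSOMES))
  per_chrom <- per_chrom[per_chrom > 0]
  carriers <- unique(variants[, c("patient_id", "gene")])
  recurrence <- table(carriers$gene) / max(n_patients, 1L)
  zygosity <- c(het = sum(variants$zygosity == "het"),
                hom = sum(variants$zygosity == "hom"))
  structure(list(per_patient_counts = c(per_patient),
                 per_gene_events = c(per_gene),
                 per_chromosome_counts = c(per_chrom),
                 recurrence = c(recurrence),
                 zygosity_counts = zygosity,
                 n_patients = n_patients),
            class = "spex_cohort_summary")
}

#' @export
print.spex_cohort_summary <- function(x, ...) {
  cat("Cohort summary:", sum(x$per_patient_counts), "events,",
      x$n_patients, "patients,", length(x$per_gene_events), "genes\n")
  cat("  zygosity: het =", x$zygosity_counts[["het"]],
      ", hom =", x$zygosity_counts[["hom"]], "\n")
  top <- sort(x$recurrence, decreasing = TRUE)
  cat("  top recurrence:",
      paste(sprintf("%s (%.0f%%)", names(head(top, 3)),
                    100 * head(top, 3)), collapse = ", "), "\n")
  invisible(x)
}

#' Intersect two gene sets
#'
#' Symbol-normalized (case-insensitive, markdown emphasis stripped) exact
#' set intersection; returns canonical upper-case symbols.
#'
#' @param set_a,set_b character vectors of gene symbols.
#' @return sorted character vector of shared symbols.
#' @examples
#' gene_set_overlap(load_fixture("table2_snps")$gene,
#'                  load_fixture("table3_indels")$gene)
#' @export
gene_set_overlap <- function(set_a, set_b) {
  sort(intersect(unique(normalize_gene(set_a)),
                 unique(normalize_gene(set_b))))
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Computed by full hypergeometric enumeration: with margins fixed, all
#' admissible tables are enumerated and the probabilities of those no more
#' likely than the observed table are summed (standard two-sided
#' convention, with the usual relative tolerance on "no more likely").
#'
#' @param tab 2x2 matrix of non-negative integer counts; no margin may be
#'   empty.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_p(matrix(c(2, 2, 0, 5), 2))  # 1/6
#' @export
fisher_exact_p <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == floor(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in 2x2 table", call. = FALSE)
  }
  m <- sum(tab[1, ])          # row-1 total
  n <- sum(tab[2, ])          # row-2 total
  k <- sum(tab[, 1])          # column-1 total
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p <- sum(probs[probs <= dhyper(x, m, n, k) * (1 + 1e-7)])
  min(1, p)
}

#' Compare per-patient mutation burden between two groups
#'
#' Builds a 2x2 contingency table from per-patient event counts and a
#' two-level patient grouping, then applies the two-sided Fisher exact
#' test ([fisher_exact_p()]). Two constructions are offered (the study
#' reports Fisher tests without stating its table construction, so both
#' are provided and labeled):
#'
#' * `median_dichotomy` — patients are split at the cohort median event
#'   count (strictly above the median = high burden) and crossed with the
#'   grouping; rows are groups, columns are high/low.
#' * `pooled_events` — row 1 holds total events per group, row 2 the
#'   number of patients per group.
#'
#' @param summary a [summarize_cohort()] result, or a named numeric vector
#'   of per-patient event counts.
#' @param grouping named character vector/factor mapping every patient to
#'   one of exactly two group labels.
#' @param construction `"median_dichotomy"` or `"pooled_events"`.
#' @return object of class `spex_group_comparison`: list with `grouping`,
#'   `table`, `construction`, `p_value`.
#' @examples
#' pts <- load_fixture("table1_patients")
#' s <- summarize_cohort(load_fixture("table2_snps"), pts)
#' grp <- setNames(ifelse(pts$metastasis, "metastatic", "non-metastatic"),
#'                 pts$patient_id)
#' fisher_group_test(s, grp)$p_value
#' @export
fisher_group_test <- function(summary, grouping,
                              construction = c("median_dichotomy",
                                               "pooled_events")) {
  construction <- match.arg(construction)
  counts <- if (inherits(summary, "spex_cohort_summary")) {
    summary$per_patient_counts
  } else {
    summary
  }
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  grouping <- setNames(as.character(grouping), names(grouping))
  levels <- sort(unique(grouping))
  if (length(levels) != 2) {
    stop("grouping must have exactly two levels", call. = FALSE)
  }
  # patients absent from the count table carry zero events
  all_ids <- names(grouping)
  full <- setNames(rep(0, length(all_ids)), all_ids)
  known <- intersect(names(counts), all_ids)
  if (length(known) < length(counts)) {
    stop("counts include patients missing from grouping", call. = FALSE)
  }
  full[known] <- counts[known]
  g <- grouping[all_ids]

  if (construction == "median_dichotomy") {
    high <- full > median(full)
    tab <- rbind(c(sum(high & g == levels[1]), sum(!high & g == levels[1])),
                 c(sum(high & g == levels[2]), sum(!high & g == levels[2])))
    dimnames(tab) <- list(group = levels, burden = c("high", "low"))
  } else {
    tab <- rbind(events = c(sum(full[g == levels[1]]),
                            sum(full[g == levels[2]])),
                 patients = c(sum(g == levels[1]), sum(g == levels[2])))
    colnames(tab) <- levels
  }
  structure(list(grouping = g, table = tab, construction = construction,
                 p_value = fisher_exact_p(tab)),
            class = "spex_group_comparison")
}

#' @export
print.spex_group_comparison <- function(x, ...) {
  cat("Fisher exact group comparison (", x$construction, ")\n", sep = "")
  print(x$table)
  cat("two-sided p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Read a gene-gene edge table
#'
#' TSV with columns `gene_a`, `gene_b`, `score` (confidence in `[0, 1]`).
#'
#' @param path input file.
#' @return data.frame of edges.
#' @export
read_edge_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  for (col in c("gene_a", "gene_b", "score")) {
    if (!col %in% names(df)) {
      stop(sprintf("%s: missing mandatory column '%s'", basename(path), col),
           call. = FALSE)
    }
  }
  df$score <- as.numeric(df$score)
  stopifnot(all(df$score >= 0 & df$score <= 1))
  df
}

#' Rank interaction-network hubs by degree
#'
#' Keeps edges with confidence strictly above `min_score`, builds the
#' undirected gene graph and ranks genes by degree, ties broken
#' alphabetically. Self-edges are rejected.
#'
#' @param edges data.frame with `gene_a`, `gene_b`, `score`.
#' @param min_score strict confidence threshold (edges with
#'   `score > min_score` are kept); default 0.7.
#' @return data.frame with `gene` and `degree`, ordered by decreasing
#'   degree then alphabetically.
#' @examples
#' edges <- data.frame(gene_a = "CTNNB1",
#'                     gene_b = c("USP9X", "EP400", "HTT"), score = 0.95)
#' network_hub_summary(edges)
#' @export
network_hub_summary <- function(edges, min_score = 0.7) {
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(edges)))
  edges$gene_a <- normalize_gene(edges$gene_a)
  edges$gene_b <- normalize_gene(edges$gene_b)
  if (any(edges$gene_a == edges$gene_b)) {
    stop("self-edge: gene_a must differ from gene_b", call. = FALSE)
  }
  kept <- edges[edges$score > min_score, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(data.frame(gene = character(0), degree = integer(0)))
  }
  g <- igraph::graph_from_data_frame(kept[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  deg <- igraph::degree(g)
  out <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
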