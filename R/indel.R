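#' Build a transcript model for indel classification
#'
#' A transcript model is the coordinate frame in which coding indels are
#' classified: an ordered set of non-overlapping CDS intervals on one
#' chromosome plus the derived canonical 2-bp splice windows (the GT donor
#' and AG acceptor dinucleotides) flanking each internal exon boundary.
#' On the minus strand the donor window sits at the genomically-high end
#' of each intron and the acceptor at the low end.
#'
#' @param transcript_id identifier string.
#' @param chromosome chromosome the model lives on.
#' @param strand `"+"` or `"-"`.
#' @param cds_starts,cds_ends 1-based inclusive CDS interval bounds,
#'   sorted, non-overlapping; total CDS length must be at least one codon.
#' @param chrom_length optional chromosome length; positions beyond it are
#'   rejected by [classify_indel()].
#' @return an object of class `spex_transcript`.
#' @examples
#' m <- transcript_model("tx1", "chr1", "+", c(101, 301), c(200, 400))
#' m$donor_windows
#' @export
transcript_model <- function(transcript_id, chromosome, strand,
                             cds_starts, cds_ends, chrom_length = NULL) {
  stopifnot(strand %in% c("+", "-"),
            length(cds_starts) == length(cds_ends),
            length(cds_starts) >= 1,
            all(cds_starts <= cds_ends))
  chromosome <- normalize_chromosome(chromosome)
  o <- order(cds_starts)
  cds_starts <- as.integer(cds_starts[o])
  cds_ends <- as.integer(cds_ends[o])
  if (any(cds_starts[-1] <= cds_ends[-length(cds_ends)])) {
    stop("CDS intervals must be non-overlapping", call. = FALSE)
  }
  lens <- cds_ends - cds_starts + 1L
  if (sum(lens) < 3L) stop("total CDS length must be >= 3", call. = FALSE)

  n <- length(cds_starts)
  donor <- acceptor <- data.frame(start = integer(0), end = integer(0))
  if (n > 1) {
    high <- data.frame(start = cds_starts[-1] - 2L, end = cds_starts[-1] - 1L)
    low <- data.frame(start = cds_ends[-n] + 1L, end = cds_ends[-n] + 2L)
    if (strand == "+") {
      donor <- low      # 5' intron end follows the upstream exon
      acceptor <- high
    } else {
      donor <- high     # transcription runs high -> low
      acceptor <- low
    }
  }
  structure(list(transcript_id = transcript_id, chromosome = chromosome,
                 strand = strand,
                 cds_intervals = data.frame(start = cds_starts,
                                            end = cds_ends),
                 donor_windows = donor, acceptor_windows = acceptor,
                 cds_length = sum(lens),
                 chrom_length = chrom_length),
            class = "spex_transcript")
}

#' Read a transcript model from a GFF3 CDS subset
#'
#' Minimal GFF3 reader: keeps `CDS` feature rows of one seqid/strand and
#' assembles them into a [transcript_model()].
#'
#' @param path GFF3 file containing CDS features for a single transcript.
#' @return an object of class `spex_transcript`.
#' @export
read_transcript_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t")
  cds <- Filter(function(p) length(p) >= 8 && p[3] == "CDS", parts)
  if (length(cds) == 0) stop("no CDS features in ", path, call. = FALSE)
  chrom <- unique(vapply(cds, `[`, character(1), 1L))
  strand <- unique(vapply(cds, `[`, character(1), 7L))
  if (length(chrom) > 1 || length(strand) > 1) {
    stop("GFF3 CDS features span multiple seqids or strands", call. = FALSE)
  }
  id <- sub(".*ID=([^;]+).*", "\\1", vapply(cds, function(p) {
    if (length(p) >= 9) p[9] else "cds"
  }, character(1))[1])
  transcript_model(id, chrom, strand,
                   as.integer(vapply(cds, `[`, character(1), 4L)),
                   as.integer(vapply(cds, `[`, character(1), 5L)))
}

# transcript (5'->3') coordinate of a genomic base inside the CDS; NA outside
transcript_coord <- function(model, g) {
  iv <- model$cds_intervals
  cum_before <- c(0L, cumsum(iv$end - iv$start + 1L))
  i <- findInterval(g, iv$start)
  out <- rep(NA_integer_, length(g))
  ok <- i >= 1 & g <= iv$end[pmax(i, 1L)]
  t_plus <- cum_before[i[ok]] + g[ok] - iv$start[i[ok]] + 1L
  out[ok] <- if (model$strand == "+") t_plus else model$cds_length - t_plus + 1L
  out
}

in_cds <- function(model, g) !is.na(transcript_coord(model, g))

span_overlaps <- function(s, e, windows) {
  nrow(windows) > 0 && any(s <= windows$end & e >= windows$start)
}

insertion_hits_window <- function(b, windows) {
  # an insertion between b and b+1 falls strictly inside a 2-bp window
  nrow(windows) > 0 && any(b == windows$start)
}

#' Classify one coding indel
#'
#' Places an anchored indel (first base of ref/alt shared, VCF style) in a
#' transcript model and assigns one of the functional categories used for
#' the study's indel table, with its impact tier:
#'
#' * `SSD` / `SSA` (High) — the edit disrupts a splice donor/acceptor
#'   dinucleotide; splice classification takes precedence over coding
#'   classification, since a splice hit is High impact irrespective of
#'   reading frame.
#' * `FS` (High) — the net coding-length change is not a multiple of 3.
#' * `CD` / `CI` (Moderate) — in-frame deletion of whole codons aligned to
#'   the reading frame / insertion at a codon boundary.
#' * `C_and_D` / `C_and_I` (Moderate) — in-frame events that straddle
#'   codon boundaries, altering a flanking codon as well.
#' * `noncoding` (Low) — the edit touches neither CDS nor splice windows.
#'
#' Reading-frame positions are accumulated across CDS intervals and are
#' strand-aware (minus-strand frames counted from the genomically-high
#' end of the CDS).
#'
#' @param variant a one-row variant table (or list) with `chromosome`,
#'   `position`, `ref_allele`, `alt_allele`.
#' @param model a [transcript_model()].
#' @return list with `category`, `impact`, `net_length_change`.
#' @examples
#' m <- transcript_model("tx", "chr1", "+", 101, 400)
#' classify_indel(list(chromosome = "chr1", position = 150,
#'                     ref_allele = "T", alt_allele = "TG"), m)$category
#' @export
classify_indel <- function(variant, model) {
  stopifnot(inherits(model, "spex_transcript"))
  chrom <- normalize_chromosome(variant$chromosome[1])
  pos <- as.integer(variant$position[1])
  ref <- toupper(as.character(variant$ref_allele[1]))
  alt <- toupper(as.character(variant$alt_allele[1]))
  if (nchar(ref) == nchar(alt)) stop("not an indel", call. = FALSE)
  if (chrom != model$chromosome) {
    stop("variant chromosome ", chrom, " does not match model chromosome ",
         model$chromosome, call. = FALSE)
  }
  if (!is.null(model$chrom_length) && pos > model$chrom_length) {
    stop("position outside model chromosome span", call. = FALSE)
  }
  net <- nchar(alt) - nchar(ref)

  # anchored decomposition: common prefix, then deleted span / inserted tail
  k <- common_prefix_len(ref, alt)
  stopifnot(k >= 1L)
  del_start <- pos + k
  del_end <- pos + nchar(ref) - 1L
  has_del <- del_end >= del_start
  ins_len <- nchar(alt) - k
  ins_after <- pos + k - 1L     # insertion lands between ins_after and +1

  result <- function(category) {
    impact <- switch(category,
                     FS = , SSD = , SSA = "High",
                     CD = , CI = , C_and_D = , C_and_I = "Moderate",
                     noncoding = "Low")
    list(category = category, impact = impact, net_length_change = net)
  }

  if (has_del) {
    if (span_overlaps(del_start, del_end, model$donor_windows)) {
      return(result("SSD"))
    }
    if (span_overlaps(del_start, del_end, model$acceptor_windows)) {
      return(result("SSA"))
    }
  } else {
    if (insertion_hits_window(ins_after, model$donor_windows)) {
      return(result("SSD"))
    }
    if (insertion_hits_window(ins_after, model$acceptor_windows)) {
      return(result("SSA"))
    }
  }

  if (has_del) {
    del_pos <- del_start:del_end
    coding_del <- sum(in_cds(model, del_pos))
    ins_coding <- ins_len > 0 && coding_del > 0
    coding_change <- (if (ins_coding) ins_len else 0L) - coding_del
    if (coding_del == 0L) return(result("noncoding"))
    if (coding_change %% 3L != 0L) return(result("FS"))
    if (ins_len > 0) {
      # deletion plus insertion: flanking codons necessarily rewritten
      return(result(if (net < 0) "C_and_D" else "C_and_I"))
    }
    if (coding_del < length(del_pos)) return(result("C_and_D"))
    t <- transcript_coord(model, del_pos)
    tmin <- min(t); tmax <- max(t)
    aligned <- (tmin %% 3L == 1L) && (tmax %% 3L == 0L)
    return(result(if (aligned) "CD" else "C_and_D"))
  }

  # pure insertion between ins_after and ins_after + 1
  if (!in_cds(model, ins_after) || !in_cds(model, ins_after + 1L)) {
    return(result("noncoding"))
  }
  if (ins_len %% 3L != 0L) return(result("FS"))
  j <- min(transcript_coord(model, ins_after),
           transcript_coord(model, ins_after + 1L))
  result(if (j %% 3L == 0L) "CI" else "C_and_I")
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  ca <- substring(a, 1:n, 1:n)
  cb <- substring(b, 1:n, 1:n)
  d <- which(ca != cb)
  if (length(d) == 0) n else d[1] - 1L
}

#' Classify every indel in a variant table
#'
#' Applies [classify_indel()] row-wise; SNP rows are rejected.
#'
#' @param variants variant table of indels on the model's chromosome.
#' @param model a [transcript_model()].
#' @return `variants` with `category`, `impact` and `net_length_change`
#'   columns appended.
#' @export
classify_indels <- function(variants, model) {
  variants <- as_variant_table(variants)
  res <- lapply(seq_len(nrow(variants)), function(i) {
    classify_indel(variants[i, ], model)
  })
  variants$category <- vapply(res, `[[`, character(1), "category")
  variants$impact <- vapply(res, `[[`, character(1), "impact")
  variants$net_length_change <- vapply(res, function(r) {
    as.integer(r$net_length_change)
  }, integer(1))
  variants
}

normalize_category <- function(x) {
  x <- gsub("[[:space:]]", "", as.character(x))
  x[x %in% c("C&D", "CandD", "C_and_D")] <- "C_and_D"
  x[x %in% c("C&I", "CandI", "C_and_I")] <- "C_and_I"
  bad <- !x %in% INDEL_CATEGORIES
  if (any(bad)) {
    stop("unknown indel category: ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Summarize indel classifications
#'
#' Histograms of functional categories and impact tiers, plus impact
#' counts per chromosome when a `chromosome` column is present. Accepts
#' either the output of [classify_indels()] or a fixture table carrying
#' printed `category`/`impact` columns (printed spellings like `"C & D"`
#' are normalized).
#'
#' @param classifications data.frame with `category` and `impact` columns.
#' @return list with `category` (named counts over all categories),
#'   `impact` (High/Moderate/Low counts) and `by_chromosome` (impact-by-
#'   chromosome table, or `NULL`).
#' @examples
#' impact_summary(load_fixture("table3_indels"))$impact
#' @export
impact_summary <- function(classifications) {
  stopifnot(is.data.frame(classifications),
            all(c("category", "impact") %in% names(classifications)))
  cat_norm <- normalize_category(classifications$category)
  impact <- as.character(classifications$impact)
  stopifnot(all(impact %in% c("High", "Moderate", "Low")))
  category_counts <- table(factor(cat_norm, levels = INDEL_CATEGORIES))
  impact_counts <- table(factor(impact, levels = c("High", "Moderate", "Low")))
  by_chrom <- NULL
  if ("chromosome" %in% names(classifications) && nrow(classifications)) {
    chrom <- normalize_chromosome(classifications$chromosome)
    by_chrom <- table(factor(impact, levels = c("High", "Moderate", "Low")),
                      factor(chrom, levels = CHROMOSOMES))
    by_chrom <- by_chrom[, colSums(by_chrom) > 0, drop = FALSE]
  }
  list(category = c(category_counts), impact = c(impact_counts),
       by_chromosome = by_chrom)
}
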