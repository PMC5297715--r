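#' @name variant-table
#' @title Variant tables
#'
#' @description
#' The atom of every analysis in this package is one called variant event,
#' stored as a row of a plain `data.frame` with (at least) the columns
#'
#' * `patient_id` — subject carrying the event,
#' * `gene` — HGNC-style symbol, `"unknown"` allowed,
#' * `variant_class` — `"snp"` or `"indel"`,
#' * `consequence` — one of `missense`, `synonymous`, `frameshift`,
#'   `inframe`, `splice`, `noncoding`, `other`,
#' * `transcript_change`, `codon_change` — free-text annotation,
#' * `chromosome` — `chr1..chr22`, `chrX`, `chrY`,
#' * `position` — 1-based (VCF convention),
#' * `ref_allele`, `alt_allele` — strings over `ACGT`; the first base is a
#'   shared anchor for indels,
#' * `zygosity` — `"het"` or `"hom"`,
#' * `population_freq` — fraction in `[0, 1]`, `NA` when unknown.
#'
#' Extra columns (e.g. the printed `category`/`impact` of the packaged
#' indel table) are carried along untouched.
NULL

VARIANT_COLUMNS <- c("patient_id", "gene", "variant_class", "consequence",
                     "transcript_change", "codon_change", "chromosome",
                     "position", "ref_allele", "alt_allele", "zygosity",
                     "population_freq")

MANDATORY_COLUMNS <- c("patient_id", "gene", "chromosome", "position",
                       "ref_allele", "alt_allele")

#' Validate and canonicalize a variant table
#'
#' Checks the invariants of the variant-record contract (alleles over ACGT,
#' ref != alt, position >= 1, `snp` iff both alleles are single bases) and
#' fills optional columns with defaults. Used by all readers; exported so
#' user-assembled data frames can be checked too.
#'
#' @param df data.frame with at least the mandatory columns
#'   (`patient_id`, `gene`, `chromosome`, `position`, `ref_allele`,
#'   `alt_allele`).
#' @param source optional label (file name) used in error messages.
#' @return the canonicalized data.frame, canonical columns first.
#' @export
as_variant_table <- function(df, source = "variant table") {
  stopifnot(is.data.frame(df))
  for (col in MANDATORY_COLUMNS) {
    if (!col %in% names(df)) {
      stop(sprintf("%s: missing mandatory column '%s'", source, col),
           call. = FALSE)
    }
  }
  df$patient_id <- as.character(df$patient_id)
  df$gene <- gsub("[*]", "", as.character(df$gene))
  df$chromosome <- if (nrow(df)) normalize_chromosome(df$chromosome) else character(0)
  df$position <- as.integer(df$position)
  df$ref_allele <- toupper(as.character(df$ref_allele))
  df$alt_allele <- toupper(as.character(df$alt_allele))

  bad <- !grepl("^[ACGT]+$", df$ref_allele) | !grepl("^[ACGT]+$", df$alt_allele)
  if (any(bad)) {
    stop(sprintf("%s: allele with characters outside {A,C,G,T} at line %s",
                 source, paste(which(bad) + 1L, collapse = ", ")),
         call. = FALSE)
  }
  if (any(is.na(df$position) | df$position < 1L)) {
    stop(sprintf("%s: position must be a 1-based integer", source),
         call. = FALSE)
  }
  if (any(df$ref_allele == df$alt_allele)) {
    stop(sprintf("%s: ref_allele equals alt_allele at line %s", source,
                 paste(which(df$ref_allele == df$alt_allele) + 1L,
                       collapse = ", ")), call. = FALSE)
  }

  is_snp <- nchar(df$ref_allele) == 1L & nchar(df$alt_allele) == 1L
  if (!"variant_class" %in% names(df) || all(is.na(df$variant_class))) {
    df$variant_class <- ifelse(is_snp, "snp", "indel")
  } else {
    df$variant_class <- as.character(df$variant_class)
    mismatch <- (df$variant_class == "snp") != is_snp
    if (any(mismatch, na.rm = TRUE)) {
      stop(sprintf("%s: variant_class inconsistent with allele lengths at line %s",
                   source, paste(which(mismatch) + 1L, collapse = ", ")),
           call. = FALSE)
    }
  }
  if (!"consequence" %in% names(df)) df$consequence <- rep("other", nrow(df))
  df$consequence <- as.character(df$consequence)
  unknown_csq <- !df$consequence %in% CONSEQUENCES
  if (any(unknown_csq)) {
    stop(sprintf("%s: unknown consequence '%s'", source,
                 df$consequence[which(unknown_csq)[1]]), call. = FALSE)
  }
  if (!"transcript_change" %in% names(df)) {
    df$transcript_change <- rep("", nrow(df))
  }
  if (!"codon_change" %in% names(df)) df$codon_change <- rep("", nrow(df))
  df$transcript_change[is.na(df$transcript_change)] <- ""
  df$codon_change[is.na(df$codon_change)] <- ""
  if (!"zygosity" %in% names(df)) df$zygosity <- rep("het", nrow(df))
  df$zygosity <- as.character(df$zygosity)
  if (!all(df$zygosity %in% c("het", "hom"))) {
    stop(sprintf("%s: zygosity must be 'het' or 'hom'", source), call. = FALSE)
  }
  if (!"population_freq" %in% names(df)) {
    df$population_freq <- rep(NA_real_, nrow(df))
  }
  df$population_freq <- suppressWarnings(as.numeric(df$population_freq))
  out_of_range <- !is.na(df$population_freq) &
    (df$population_freq < 0 | df$population_freq > 1)
  if (any(out_of_range)) {
    stop(sprintf("%s: population_freq outside [0,1]", source), call. = FALSE)
  }

  extra <- setdiff(names(df), VARIANT_COLUMNS)
  df <- df[, c(VARIANT_COLUMNS, extra), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a variant table from TSV or VCF
#'
#' TSV input must carry a header row naming the variant-record columns (see
#' [variant-table]); unparseable `population_freq` entries become `NA`
#' (unknown). VCF input (v4.x, per-sample GT) yields one record per
#' sample-by-site carrier call: `0/1`-style genotypes become `het`,
#' `1/1`-style become `hom`, `0/0` and missing genotypes are dropped, and
#' the INFO `AF` field (when present) is used as `population_freq`.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return a variant table in file order (TSV) or site-major order (VCF).
#' @examples
#' tsv <- system.file("extdata", "table2_snps.tsv", package = "spex")
#' head(read_variant_table(tsv))
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    df <- read.delim(path, sep = "\t", header = TRUE,
                     colClasses = "character", na.strings = c("NA", ""),
                     check.names = FALSE, quote = "")
    # restore empty-string semantics for the free-text columns
    for (col in intersect(c("transcript_change", "codon_change"), names(df))) {
      df[[col]][is.na(df[[col]])] <- ""
    }
    return(as_variant_table(df, source = basename(path)))
  }
  read_variant_vcf(path)
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(as_variant_table(empty_variant_table(), source = basename(path)))
  }
  alt <- vapply(strsplit(fix$ALT, ","), `[`, character(1), 1L)
  af <- tryCatch(
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "AF"))),
    error = function(e) rep(NA_real_, nrow(fix)))
  if (length(af) != nrow(fix)) af <- rep(NA_real_, nrow(fix))
  gene <- tryCatch(vcfR::extract.info(vcf, element = "GENE"),
                   error = function(e) rep(NA_character_, nrow(fix)))
  if (length(gene) != nrow(fix)) gene <- rep(NA_character_, nrow(fix))
  gene[is.na(gene)] <- "unknown"

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no per-sample GT field", call. = FALSE)
  records <- list()
  for (s in colnames(gt)) {
    g <- gt[, s]
    alleles <- strsplit(gsub("\\|", "/", g), "/")
    carrier <- vapply(alleles, function(a) {
      any(a != "0" & a != "." & !is.na(a))
    }, logical(1))
    carrier[is.na(g)] <- FALSE
    if (!any(carrier)) next
    zyg <- vapply(alleles[carrier], function(a) {
      a <- a[a != "."]
      if (length(unique(a)) == 1L && all(a != "0")) "hom" else "het"
    }, character(1))
    records[[s]] <- data.frame(
      patient_id = s,
      gene = gene[carrier],
      chromosome = fix$CHROM[carrier],
      position = as.integer(fix$POS[carrier]),
      ref_allele = fix$REF[carrier],
      alt_allele = alt[carrier],
      zygosity = zyg,
      population_freq = af[carrier],
      stringsAsFactors = FALSE)
  }
  if (length(records) == 0) {
    return(as_variant_table(empty_variant_table(), source = basename(path)))
  }
  as_variant_table(do.call(rbind, records), source = basename(path))
}

empty_variant_table <- function() {
  df <- data.frame(patient_id = character(0), gene = character(0),
                   variant_class = character(0), consequence = character(0),
                   transcript_change = character(0), codon_change = character(0),
                   chromosome = character(0), position = integer(0),
                   ref_allele = character(0), alt_allele = character(0),
                   zygosity = character(0), population_freq = numeric(0),
                   stringsAsFactors = FALSE)
  df
}

#' Write a variant table as TSV
#'
#' Inverse of [read_variant_table()]; unknown `population_freq` is written
#' as `NA`. A write/read round trip is the identity on all fields.
#'
#' @param variants variant table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  variants <- as_variant_table(variants)
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Load a packaged study table
#'
#' The package ships the study's printed tables as plain-text fixtures:
#'
#' * `table1_patients` — nine patients' clinicopathological metadata
#'   (gender, age, tumor size in mm, TNM stage, location, distant
#'   metastasis, CA19-9 status, procedure). `"no abnormal"` CA19-9 is kept
#'   literally; an unreported size is `NA`.
#' * `table2_snps` — 65 prominent somatic SNP events across the nine
#'   patients (gene, transcript and codon change, chromosome, alleles,
#'   zygosity).
#' * `table3_indels` — 56 pooled indel events with their printed functional
#'   `category` (FS, CD, CI, C & D, C & I, SSD) and `impact` tier; the
#'   table pools events across subjects, so `patient_id` is `"cohort"`.
#'
#' The printed tables carry no genomic coordinates or population
#' frequencies, so the `position` column holds synthetic placeholder
#' coordinates (distinct, deterministic, one per row) and
#' `population_freq` is `NA`; per-gene, per-chromosome and per-patient
#' statistics are unaffected.
#'
#' @param name one of `"table1_patients"`, `"table2_snps"`,
#'   `"table3_indels"`.
#' @return a patient metadata data.frame for `table1_patients`, otherwise a
#'   variant table.
#' @examples
#' nrow(load_fixture("table2_snps"))   # 65
#' @export
load_fixture <- function(name = c("table1_patients", "table2_snps",
                                  "table3_indels")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "spex",
                      mustWork = TRUE)
  if (name == "table1_patients") {
    df <- read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                     stringsAsFactors = FALSE)
    df$age_years <- as.integer(df$age_years)
    df$size_mm <- as.integer(df$size_mm)
    df$metastasis <- as.logical(df$metastasis)
    stopifnot(all(df$age_years > 0), all(df$size_mm > 0, na.rm = TRUE))
    return(df)
  }
  read_variant_table(path, dialect = "tsv")
}

#' Write homozygous regions as BED
#'
#' Emits BED3+2 (`chrom`, 0-based half-open `start`/`end`, region length in
#' bp, marker count) preceded by a `#` header comment. Input must already
#' be sorted by chromosome then start; regions are stored 1-based inclusive
#' internally and converted on export.
#'
#' @param regions data.frame with `chromosome`, `start_bp`, `end_bp`,
#'   `length_bp`, `n_markers` (as produced by [map_homozygosity()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  needed <- c("chromosome", "start_bp", "end_bp", "length_bp", "n_markers")
  stopifnot(all(needed %in% names(regions)))
  if (nrow(regions) > 1) {
    r <- chromosome_rank(regions$chromosome)
    o <- order(r, regions$start_bp)
    if (!identical(o, seq_len(nrow(regions)))) {
      stop("unsorted regions: sort by chromosome then start before writing",
           call. = FALSE)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tlength_bp\tn_markers", con)
  if (nrow(regions)) {
    lines <- sprintf("%s\t%d\t%d\t%d\t%d", regions$chromosome,
                     as.integer(regions$start_bp) - 1L,
                     as.integer(regions$end_bp),
                     as.integer(regions$length_bp),
                     as.integer(regions$n_markers))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' Converts the 0-based half-open BED spans back to the package's 1-based
#' inclusive convention.
#'
#' @param path BED file.
#' @return data.frame with `chromosome`, `start_bp`, `end_bp`, `length_bp`,
#'   `n_markers`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(chromosome = character(0), start_bp = integer(0),
                      end_bp = integer(0), length_bp = integer(0),
                      n_markers = integer(0)))
  }
  parts <- do.call(rbind, strsplit(lines, "\t"))
  data.frame(chromosome = parts[, 1],
             start_bp = as.integer(parts[, 2]) + 1L,
             end_bp = as.integer(parts[, 3]),
             length_bp = as.integer(parts[, 4]),
             n_markers = as.integer(parts[, 5]),
             stringsAsFactors = FALSE)
}

#' Read a marker table for homozygosity mapping
#'
#' TSV input needs columns `chromosome`, `position`, `depth`,
#' `variant_reads`. VCF input uses the per-sample `DP` and `AD` FORMAT
#' fields (first sample by default); `variant_reads` is the sum of
#' non-reference allele depths.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param sample sample name for VCF input; defaults to the first sample.
#' @return data.frame with `chromosome`, `position`, `depth`,
#'   `variant_reads`.
#' @export
read_marker_table <- function(path, dialect = c("tsv", "vcf"), sample = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    for (col in c("chromosome", "position", "depth", "variant_reads")) {
      if (!col %in% names(df)) {
        stop(sprintf("%s: missing mandatory column '%s'", basename(path), col),
             call. = FALSE)
      }
    }
    df$chromosome <- normalize_chromosome(df$chromosome)
    df$position <- as.integer(df$position)
    df$depth <- as.integer(df$depth)
    df$variant_reads <- as.integer(df$variant_reads)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    ad <- vcfR::extract.gt(vcf, element = "AD")
    if (is.null(dp) || is.null(ad)) {
      stop("VCF marker input requires DP and AD FORMAT fields", call. = FALSE)
    }
    sample <- sample %||% colnames(dp)[1]
    alt_reads <- vapply(strsplit(ad[, sample], ","), function(a) {
      a <- suppressWarnings(as.integer(a))
      sum(a[-1], na.rm = TRUE)
    }, integer(1))
    df <- data.frame(chromosome = normalize_chromosome(fix$CHROM),
                     position = as.integer(fix$POS),
                     depth = as.integer(dp[, sample]),
                     variant_reads = alt_reads,
                     stringsAsFactors = FALSE)
  }
  if (any(df$variant_reads > df$depth, na.rm = TRUE)) {
    stop("variant_reads exceeds depth", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}
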