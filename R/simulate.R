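# hg19-like autosome lengths (bp), used as the default simulation genome
DEFAULT_GENOME <- data.frame(
  chromosome = paste0("chr", 1:22),
  length_bp = c(249250621, 243199373, 198022430, 191154276, 180915260,
                171115067, 159138663, 146364022, 141213431, 135534747,
                135006516, 133851895, 115169878, 107349540, 102531392,
                90354753, 81195210, 78077248, 59128983, 63025520,
                48129895, 51304566),
  stringsAsFactors = FALSE)

# fixed 200-symbol vocabulary so recurrence statistics are meaningful
GENE_VOCABULARY <- sprintf("SYNG%03d", 1:200)

#' Configure the synthetic cohort and marker-map generator
#'
#' One configuration object drives both [generate_paired_cohort()] (paired
#' tumor/normal variant tables with truth labels) and
#' [generate_marker_map()] (autosomal marker maps with planted homozygous
#' stretches under a binomial read-sampling model). Defaults emulate the
#' study design: nine patients, a driver gene hit in every tumor, a 0.5%
#' population-frequency landscape, and exome-like marker maps.
#'
#' @param seed integer seed; identical configurations generate
#'   byte-identical outputs.
#' @param n_patients number of tumor/normal pairs.
#' @param genome data.frame with `chromosome`, `length_bp`.
#' @param germline_rate,somatic_rate events per patient per genome
#'   (germline events appear in both members of a pair, somatic in the
#'   tumor only).
#' @param fraction_indel fraction of events simulated as indels.
#' @param fraction_synonymous,fraction_noncoding consequence mix; the
#'   remainder is functional (missense for SNPs, frameshift/in-frame for
#'   indels). Indels drawn silent are emitted as noncoding.
#' @param fraction_common fraction of variants assigned a population
#'   frequency above 0.005 (the filter threshold); assigned independently
#'   of germline/somatic origin, as database membership is in real data.
#' @param fraction_novel fraction of rare variants with unknown (`NA`)
#'   frequency.
#' @param driver_gene gene receiving one somatic missense per patient with
#'   probability `driver_prob` (emulating the universally mutated driver).
#' @param marker_spacing_bp mean inter-marker distance (exponential gaps).
#' @param mean_depth mean marker depth (Poisson).
#' @param het_truth_rate probability that a marker outside planted regions
#'   is truly heterozygous (exome variant sites are roughly two-thirds
#'   heterozygous; inside plants every marker is homozygous).
#' @param error_rate per-read sequencing error; homozygous markers draw
#'   `variant_reads ~ Binomial(depth, 1 - error_rate)`, heterozygous
#'   markers `Binomial(depth, 0.5)`.
#' @param roh_plants `NULL`, or data.frame with `chromosome`, `start`,
#'   `end` giving planted homozygous stretches (must lie within the
#'   genome).
#' @return an object of class `spex_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_patients = 9L, genome = DEFAULT_GENOME,
                       germline_rate = 500L, somatic_rate = 50L,
                       fraction_indel = 0.3, fraction_synonymous = 0.25,
                       fraction_noncoding = 0.15, fraction_common = 0.3,
                       fraction_novel = 0.3, driver_gene = "CTNNB1",
                       driver_prob = 1.0, marker_spacing_bp = 5000,
                       mean_depth = 30L, het_truth_rate = 0.65,
                       error_rate = 0.01, roh_plants = NULL) {
  stopifnot(is_count(seed), is_count(n_patients), n_patients >= 1,
            is.data.frame(genome),
            all(c("chromosome", "length_bp") %in% names(genome)),
            nrow(genome) >= 1, all(genome$length_bp > 0),
            germline_rate >= 0, somatic_rate >= 0,
            fraction_indel >= 0, fraction_indel <= 1,
            fraction_synonymous >= 0, fraction_noncoding >= 0,
            fraction_synonymous + fraction_noncoding <= 1,
            fraction_common >= 0, fraction_common <= 1,
            fraction_novel >= 0, fraction_novel <= 1,
            driver_prob >= 0, driver_prob <= 1,
            marker_spacing_bp > 0, mean_depth > 0,
            het_truth_rate >= 0, het_truth_rate <= 1,
            error_rate >= 0, error_rate < 0.5)
  genome$chromosome <- normalize_chromosome(genome$chromosome)
  if (!is.null(roh_plants)) {
    stopifnot(is.data.frame(roh_plants),
              all(c("chromosome", "start", "end") %in% names(roh_plants)))
    roh_plants$chromosome <- normalize_chromosome(roh_plants$chromosome)
    m <- match(roh_plants$chromosome, genome$chromosome)
    if (any(is.na(m)) || any(roh_plants$start < 1) ||
        any(roh_plants$end > genome$length_bp[m]) ||
        any(roh_plants$start > roh_plants$end)) {
      stop("roh_plants must lie within the genome", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 genome = genome, germline_rate = as.integer(germline_rate),
                 somatic_rate = as.integer(somatic_rate),
                 fraction_indel = fraction_indel,
                 fraction_synonymous = fraction_synonymous,
                 fraction_noncoding = fraction_noncoding,
                 fraction_common = fraction_common,
                 fraction_novel = fraction_novel,
                 driver_gene = driver_gene, driver_prob = driver_prob,
                 marker_spacing_bp = marker_spacing_bp,
                 mean_depth = mean_depth, het_truth_rate = het_truth_rate,
                 error_rate = error_rate, roh_plants = roh_plants),
            class = "spex_sim_config")
}

sample_loci <- function(config, n) {
  g <- config$genome
  chrom_idx <- sample.int(nrow(g), n, replace = TRUE,
                          prob = g$length_bp / sum(g$length_bp))
  pos <- 1L + floor(runif(n) * g$length_bp[chrom_idx])
  data.frame(chromosome = g$chromosome[chrom_idx], position = as.integer(pos),
             stringsAsFactors = FALSE)
}

BASES <- c("A", "C", "G", "T")

simulate_events <- function(config, n, patient_id, origin) {
  loci <- sample_loci(config, n)
  is_indel <- runif(n) < config$fraction_indel
  ref <- BASES[sample.int(4L, n, replace = TRUE)]
  alt <- character(n)
  for (i in which(!is_indel)) {
    alt[i] <- sample(setdiff(BASES, ref[i]), 1L)
  }
  for (i in which(is_indel)) {
    tail_len <- sample.int(6L, 1L)
    tail <- paste(BASES[sample.int(4L, tail_len, replace = TRUE)],
                  collapse = "")
    if (runif(1) < 0.5) {
      alt[i] <- paste0(ref[i], tail)                       # insertion
    } else {
      alt[i] <- ref[i]
      ref[i] <- paste0(alt[i], tail)                       # deletion
    }
  }
  u <- runif(n)
  csq <- ifelse(u < config$fraction_noncoding, "noncoding",
                ifelse(u < config$fraction_noncoding +
                         config$fraction_synonymous, "synonymous",
                       "functional"))
  csq[csq == "synonymous" & is_indel] <- "noncoding"
  functional <- csq == "functional"
  net <- nchar(alt) - nchar(ref)
  csq[functional & !is_indel] <- "missense"
  csq[functional & is_indel & net %% 3L != 0L] <- "frameshift"
  csq[functional & is_indel & net %% 3L == 0L] <- "inframe"
  common <- runif(n) < config$fraction_common
  freq <- ifelse(common, 0.005 + runif(n) * 0.195, runif(n) * 0.005)
  freq[!common & runif(n) < config$fraction_novel] <- NA_real_
  zyg <- if (origin == "germline") {
    ifelse(runif(n) < 1 / 3, "hom", "het")
  } else {
    rep("het", n)
  }
  data.frame(patient_id = rep(patient_id, n),
             gene = GENE_VOCABULARY[sample.int(length(GENE_VOCABULARY), n,
                                               replace = TRUE)],
             variant_class = ifelse(is_indel, "indel", "snp"),
             consequence = csq, transcript_change = rep("", n),
             codon_change = rep("", n),
             chromosome = loci$chromosome, position = loci$position,
             ref_allele = ref, alt_allele = alt, zygosity = zyg,
             population_freq = freq, origin = rep(origin, n),
             stringsAsFactors = FALSE)
}

#' Generate a paired tumor/normal synthetic cohort with truth labels
#'
#' For each patient, germline events are emitted into both the tumor and
#' the normal table while somatic events are tumor-only; with probability
#' `driver_prob` one extra somatic rare missense SNP in `driver_gene` is
#' added per patient. Loci are drawn uniformly across the genome
#' (length-weighted) and de-duplicated within a patient so that
#' matched-normal subtraction by locus identity is exact. The output is
#' deterministic given the configuration seed.
#'
#' @param config a [sim_config()].
#' @return list with `tumor` and `normal` variant tables (all patients,
#'   sorted by patient, chromosome, position) and `truth`, the tumor table
#'   plus an `origin` column (`"germline"` or `"somatic"`) carrying the
#'   generator's labels.
#' @examples
#' sim <- generate_paired_cohort(sim_config(seed = 2, n_patients = 3,
#'                                          germline_rate = 20,
#'                                          somatic_rate = 5))
#' table(sim$truth$origin)
#' @export
generate_paired_cohort <- function(config) {
  stopifnot(inherits(config, "spex_sim_config"))
  if (sum(config$genome$length_bp) <= 0) {
    stop("zero-length genome", call. = FALSE)
  }
  set.seed(config$seed)
  per_patient <- lapply(seq_len(config$n_patients), function(i) {
    pid <- sprintf("SIM_%02d", i)
    repeat {
      germ <- simulate_events(config, config$germline_rate, pid, "germline")
      som <- simulate_events(config, config$somatic_rate, pid, "somatic")
      if (config$driver_prob > 0 && runif(1) < config$driver_prob) {
        drv <- simulate_events(config, 1L, pid, "somatic")
        drv$gene <- config$driver_gene
        drv$variant_class <- "snp"
        drv$consequence <- "missense"
        drv$ref_allele <- "C"
        drv$alt_allele <- "T"
        drv$population_freq <- NA_real_
        drv$zygosity <- "het"
        som <- rbind(som, drv)
      }
      all_ev <- rbind(germ, som)
      if (!anyDuplicated(paste(all_ev$chromosome, all_ev$position))) {
        break   # locus collisions within a patient: redraw (rare)
      }
    }
    o <- order(chromosome_rank(all_ev$chromosome), all_ev$position)
    all_ev[o, , drop = FALSE]
  })
  truth <- do.call(rbind, per_patient)
  rownames(truth) <- NULL
  tumor <- truth[, setdiff(names(truth), "origin"), drop = FALSE]
  normal <- truth[truth$origin == "germline",
                  setdiff(names(truth), "origin"), drop = FALSE]
  rownames(normal) <- NULL
  list(tumor = as_variant_table(tumor), normal = as_variant_table(normal),
       truth = truth)
}

#' Generate a synthetic marker map with planted homozygous stretches
#'
#' Marker positions are laid down per chromosome with exponential gaps of
#' mean `marker_spacing_bp`; truth zygosity is homozygous inside
#' `roh_plants` and heterozygous with probability `het_truth_rate`
#' elsewhere; depths are Poisson around `mean_depth`; variant read counts
#' are binomial with success probability `1 - error_rate` (hom) or 0.5
#' (het). The pseudo-random stream is consumed in a fixed order
#' (positions, then zygosity, then depths, then reads), so outputs are
#' byte-identical for identical configurations.
#'
#' @param config a [sim_config()].
#' @return list with `markers` (data.frame `chromosome`, `position`,
#'   `depth`, `variant_reads`), `truth` (the markers plus a
#'   `truth_zygosity` column) and `plants` (the configured spans).
#' @export
generate_marker_map <- function(config) {
  stopifnot(inherits(config, "spex_sim_config"))
  set.seed(config$seed)
  g <- config$genome
  positions <- lapply(seq_len(nrow(g)), function(i) {
    len <- g$length_bp[i]
    n_exp <- ceiling(len / config$marker_spacing_bp * 1.2) + 50L
    pos <- cumsum(rexp(n_exp, rate = 1 / config$marker_spacing_bp))
    while (pos[length(pos)] < len) {
      pos <- c(pos, pos[length(pos)] +
                 cumsum(rexp(n_exp, rate = 1 / config$marker_spacing_bp)))
    }
    pos <- floor(pos[pos <= len - 1]) + 1L
    unique(as.integer(pos))
  })
  markers <- data.frame(
    chromosome = rep(g$chromosome, lengths(positions)),
    position = unlist(positions),
    stringsAsFactors = FALSE)

  in_plant <- rep(FALSE, nrow(markers))
  if (!is.null(config$roh_plants)) {
    for (r in seq_len(nrow(config$roh_plants))) {
      p <- config$roh_plants[r, ]
      in_plant <- in_plant | (markers$chromosome == p$chromosome &
                                markers$position >= p$start &
                                markers$position <= p$end)
    }
  }
  truth_zyg <- ifelse(in_plant, "homozygous",
                      ifelse(runif(nrow(markers)) < config$het_truth_rate,
                             "heterozygous", "homozygous"))
  depth <- rpois(nrow(markers), config$mean_depth)
  vaf <- ifelse(truth_zyg == "homozygous", 1 - config$error_rate, 0.5)
  variant_reads <- rbinom(nrow(markers), depth, vaf)
  markers$depth <- as.integer(depth)
  markers$variant_reads <- as.integer(variant_reads)
  truth <- markers
  truth$truth_zygosity <- truth_zyg
  list(markers = markers, truth = truth, plants = config$roh_plants)
}
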