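# In-code builders and independent oracles shared across the test files.

make_variants <- function(n = 1, patient_id = "P1", gene = "SYNG001",
                          consequence = "missense", chromosome = "chr1",
                          position = seq_len(n) * 1000L, ref = "A", alt = "G",
                          zygosity = "het", population_freq = NA_real_) {
  data.frame(patient_id = patient_id, gene = gene,
             consequence = consequence, chromosome = chromosome,
             position = position, ref_allele = ref, alt_allele = alt,
             zygosity = zygosity, population_freq = population_freq,
             stringsAsFactors = FALSE)
}

# a hand-built marker map data.frame ready for scan_windows
make_map <- function(calls, positions = seq_along(calls) * 1000L,
                     chromosome = "chr1", depth = 30L) {
  structure(data.frame(chromosome = chromosome, position = positions,
                       depth = depth,
                       variant_reads = ifelse(calls == "heterozygous",
                                              15L, 30L),
                       call = calls, stringsAsFactors = FALSE),
            class = c("spex_marker_map", "data.frame"))
}

random_call_map <- function(n, het_rate, seed, spacing = 1000L,
                            big_gap_rate = 0) {
  set.seed(seed)
  gaps <- spacing + rpois(n - 1, spacing / 10)
  if (big_gap_rate > 0) {
    big <- runif(n - 1) < big_gap_rate
    gaps[big] <- 600000L
  }
  calls <- sample(c("heterozygous", "homozygous", "ambiguous"), n,
                  replace = TRUE, prob = c(het_rate, 1 - het_rate - 0.02,
                                           0.02))
  make_map(calls, positions = cumsum(c(1L, gaps)))
}

write_test_vcf <- function(path, markers = FALSE) {
  if (!markers) {
    lines <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
      "chr1\t100\t.\tA\tG\t.\t.\tAF=0.010;GENE=TP53\tGT\t0/1\t0/0",
      "chr2\t200\t.\tT\tTG\t.\t.\tGENE=KRAS\tGT\t1/1\t0/1",
      "chrX\t300\t.\tC\tA\t.\t.\tAF=0.200;GENE=AR\tGT\t0/0\t0/1")
  } else {
    lines <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
      "chr1\t1000\t.\tA\tG\t.\t.\t.\tGT:DP:AD\t1/1:30:1,29",
      "chr1\t2000\t.\tC\tT\t.\t.\t.\tGT:DP:AD\t0/1:20:10,10",
      "chrX\t3000\t.\tG\tA\t.\t.\t.\tGT:DP:AD\t0/1:25:12,13")
  }
  writeLines(lines, path)
  path
}

# ---- independent oracle for the indel classifier -------------------------
# Re-derives categories from first principles on a concrete genome string:
# splice windows by direct enumeration, coding effect by editing the
# sequence, re-splicing the CDS with plain coordinate arithmetic, and
# translating before/after.

random_transcript_case <- function(seed) {
  set.seed(seed)
  # two or three exons, total CDS length a multiple of 3
  n_exon <- sample(2:3, 1)
  lens <- sample(5:20, n_exon, replace = TRUE) * 3L
  gaps <- sample(20:60, n_exon, replace = TRUE)
  starts <- integer(n_exon)
  ends <- integer(n_exon)
  cursor <- 50L
  for (i in seq_len(n_exon)) {
    starts[i] <- cursor + gaps[i]
    ends[i] <- starts[i] + lens[i] - 1L
    cursor <- ends[i]
  }
  glen <- ends[n_exon] + 50L
  genome <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                  collapse = "")
  list(genome = genome, starts = starts, ends = ends, glen = glen)
}

oracle_splice_windows <- function(starts, ends, strand) {
  n <- length(starts)
  wins <- list(donor = integer(0), acceptor = integer(0))
  if (n == 1) return(wins)
  for (i in seq_len(n - 1)) {
    low <- c(ends[i] + 1L, ends[i] + 2L)        # intron start (genomic)
    high <- c(starts[i + 1] - 2L, starts[i + 1] - 1L)  # intron end
    if (strand == "+") {
      wins$donor <- c(wins$donor, low)
      wins$acceptor <- c(wins$acceptor, high)
    } else {
      wins$donor <- c(wins$donor, high)
      wins$acceptor <- c(wins$acceptor, low)
    }
  }
  wins
}

oracle_translate <- function(seq, strand) {
  dna <- Biostrings::DNAString(seq)
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  as.character(Biostrings::translate(dna, if.fuzzy.codon = "X"))
}

splice_seq <- function(genome, starts, ends) {
  paste(substring(genome, starts, ends), collapse = "")
}

# classify an edit by brute force; returns list(frameshift=, protein_diff=)
oracle_indel_effect <- function(case, strand, pos, ref, alt) {
  genome <- case$genome
  stopifnot(substring(genome, pos, pos + nchar(ref) - 1L) == ref ||
              nchar(ref) == 1L)
  # splice hit?
  wins <- oracle_splice_windows(case$starts, case$ends, strand)
  del_span <- if (nchar(ref) > 1) (pos + 1L):(pos + nchar(ref) - 1L) else integer(0)
  hit <- function(w) {
    if (length(del_span)) any(del_span %in% w)
    else pos %in% w[seq(1, length(w), by = 2)]  # insertion inside a 2-bp win
  }
  if (hit(wins$donor)) return(list(splice = "SSD"))
  if (hit(wins$acceptor)) return(list(splice = "SSA"))

  net <- nchar(alt) - nchar(ref)
  edited <- paste0(substring(genome, 1, pos - 1L), alt,
                   substring(genome, pos + nchar(ref), nchar(genome)))
  # shift CDS intervals across the edit point (edit begins after pos)
  starts <- case$starts
  ends <- case$ends
  new_starts <- ifelse(starts > pos, starts + net, starts)
  new_ends <- ifelse(ends > pos, ends + net, ends)
  old_cds <- splice_seq(genome, starts, ends)
  new_cds <- splice_seq(edited, new_starts, new_ends)
  if ((nchar(new_cds) - nchar(old_cds)) %% 3L != 0L) {
    return(list(splice = NULL, frameshift = TRUE))
  }
  old_p <- oracle_translate(old_cds, strand)
  new_p <- oracle_translate(new_cds, strand)
  k <- (nchar(new_p) - nchar(old_p))
  diff <- "mixed"
  if (k == 0 && old_p == new_p) diff <- "none"
  if (k < 0) {
    for (i in seq_len(nchar(new_p) + 1L)) {
      cand <- paste0(substring(old_p, 1, i - 1L),
                     substring(old_p, i - k, nchar(old_p)))
      if (cand == new_p) { diff <- "pure_deletion"; break }
    }
  } else if (k > 0) {
    for (i in seq_len(nchar(old_p) + 1L)) {
      cand <- paste0(substring(new_p, 1, i - 1L),
                     substring(new_p, i + k, nchar(new_p)))
      if (cand == old_p) { diff <- "pure_insertion"; break }
    }
  }
  list(splice = NULL, frameshift = FALSE, protein_diff = diff)
}

# brute-force two-sided Fisher p from the closed-form table probability
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  logp <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(n - c1 + 1) -
      lgamma(n + 1) - lgamma(a + 1) - lgamma(b + 1) - lgamma(c + 1) -
      lgamma(d + 1)
  }
  support <- max(0, c1 - r2):min(c1, r1)
  lp <- vapply(support, logp, numeric(1))
  obs <- logp(tab[1, 1])
  min(1, sum(exp(lp[lp <= obs + log(1 + 1e-7)])))
}

map_homozygosity_from_map <- function(map, params) {
  coalesce_windows(scan_windows(map, params), map, params)
}
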