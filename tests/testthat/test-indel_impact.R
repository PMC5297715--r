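# two-exon plus-strand model: CDS = 101..200 and 301..400 on chr1
two_exon <- transcript_model("tx1", "chr1", "+", c(101L, 301L),
                             c(200L, 400L))
iv <- function(pos, ref, alt, chrom = "chr1") {
  list(chromosome = chrom, position = pos, ref_allele = ref,
       alt_allele = alt)
}

test_that("coding indels land in the printed functional categories", {
  # frame shift: net +1 inside CDS
  expect_equal(classify_indel(iv(150, "T", "TG"), two_exon)[c("category", "impact")],
               list(category = "FS", impact = "High"))
  # net +3 at a codon boundary (transcript position 3 | 4)
  expect_equal(classify_indel(iv(103, "A", "ACAG"), two_exon)$category, "CI")
  # net +3 inside a codon
  expect_equal(classify_indel(iv(104, "G", "GCAA"), two_exon)$category,
               "C_and_I")
  # whole-codon deletion (transcript 4..6) vs frame-straddling deletion
  expect_equal(classify_indel(iv(103, "GGCA", "G"), two_exon)$category, "CD")
  expect_equal(classify_indel(iv(104, "GGCA", "G"), two_exon)$category,
               "C_and_D")
  # deletion over the first two intronic bases after exon 1 = donor window
  expect_equal(classify_indel(iv(200, "AT", "A"), two_exon)[c("category", "impact")],
               list(category = "SSD", impact = "High"))
  # acceptor window before exon 2
  expect_equal(classify_indel(iv(298, "CA", "C"), two_exon)$category, "SSA")
  # intronic, away from splice windows
  expect_equal(classify_indel(iv(250, "AT", "A"), two_exon)[c("category", "impact")],
               list(category = "noncoding", impact = "Low"))

  expect_equal(classify_indel(iv(150, "GGCAGG", "G"), two_exon)$net_length_change,
               -5L)
  expect_error(classify_indel(iv(150, "A", "G"), two_exon), "not an indel")
  expect_error(classify_indel(iv(150, "T", "TG", chrom = "chr2"), two_exon),
               "chromosome")
  capped <- transcript_model("tx1", "chr1", "+", 101L, 400L,
                             chrom_length = 1000L)
  expect_error(classify_indel(iv(2000, "T", "TG"), capped), "span")
})

test_that("minus-strand reading frames count from the genomically-high end", {
  minus <- transcript_model("tx2", "chr1", "-", c(101L, 301L), c(200L, 400L))
  # transcript starts at genomic 400; deleting 398..400 removes codon 1
  expect_equal(classify_indel(iv(397, "TAAA", "T"), minus)$category, "CD")
  expect_equal(classify_indel(iv(396, "TAAA", "T"), minus)$category,
               "C_and_D")
  expect_equal(classify_indel(iv(397, "T", "TAAA"), minus)$category, "CI")
  expect_equal(classify_indel(iv(396, "T", "TAAA"), minus)$category,
               "C_and_I")
  # donor window on the minus strand is the high end of the intron
  expect_equal(classify_indel(iv(298, "CA", "C"), minus)$category, "SSD")
  expect_equal(classify_indel(iv(200, "AT", "A"), minus)$category, "SSA")
})

test_that("in-frame categories are invariant under codon-sized shifts", {
  wide <- transcript_model("tx3", "chr1", "+", 101L, 400L)
  for (shift in c(0L, 3L, 9L, 30L)) {
    expect_equal(classify_indel(iv(103L + shift, "GAAA", "G"), wide)$category,
                 "CD")
    expect_equal(classify_indel(iv(104L + shift, "GAAA", "G"), wide)$category,
                 "C_and_D")
    expect_equal(classify_indel(iv(103L + shift, "A", "AGGG"), wide)$category,
                 "CI")
  }
})

test_that("classifier agrees with a sequence-level translation oracle", {
  for (seed in 1:40) {
    case <- random_transcript_case(seed)
    model <- transcript_model("tx", "chr1", "+", case$starts, case$ends)
    set.seed(seed + 1000)
    for (rep in 1:8) {
      exon <- sample(length(case$starts), 1)
      # anchored edit fully inside one exon (margin 1 from the 3' edge)
      pos <- sample(case$starts[exon]:(case$ends[exon] - 7L), 1)
      if (runif(1) < 0.5) {
        len <- sample(1:6, 1)
        ref <- substring(case$genome, pos, pos + len)
        alt <- substring(case$genome, pos, pos)
      } else {
        ref <- substring(case$genome, pos, pos)
        alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"),
                                        sample(1:6, 1), replace = TRUE),
                                 collapse = ""))
      }
      got <- classify_indel(iv(pos, ref, alt), model)
      want <- oracle_indel_effect(case, "+", pos, ref, alt)
      expect_null(want$splice)
      if (want$frameshift) {
        expect_equal(got$category, "FS")
      } else {
        expect_true(got$category %in% c("CD", "CI", "C_and_D", "C_and_I"))
        # aligned categories must reproduce a clean protein-level diff
        if (got$category == "CD") {
          expect_equal(want$protein_diff, "pure_deletion")
        }
        if (got$category == "CI") {
          expect_equal(want$protein_diff, "pure_insertion")
        }
      }
    }
  }
})

test_that("splice classification agrees with window enumeration and wins over frame", {
  for (seed in 41:55) {
    case <- random_transcript_case(seed)
    for (strand in c("+", "-")) {
      model <- transcript_model("tx", "chr1", strand, case$starts, case$ends)
      wins <- oracle_splice_windows(case$starts, case$ends, strand)
      for (w in wins$donor[seq(1, length(wins$donor), by = 2)]) {
        got <- classify_indel(iv(w - 1L, substring(case$genome, w - 1L, w + 1L),
                                 substring(case$genome, w - 1L, w - 1L)),
                              model)
        expect_equal(got[c("category", "impact")],
                     list(category = "SSD", impact = "High"))
      }
      for (w in wins$acceptor[seq(1, length(wins$acceptor), by = 2)]) {
        got <- classify_indel(iv(w - 1L, substring(case$genome, w - 1L, w + 1L),
                                 substring(case$genome, w - 1L, w - 1L)),
                              model)
        expect_equal(got$category, "SSA")
      }
    }
  }
})

test_that("impact_summary reproduces the printed study histogram", {
  t3 <- load_fixture("table3_indels")
  s <- impact_summary(t3)
  expect_equal(s$impact[["High"]], 27)
  expect_equal(s$impact[["Moderate"]], 29)
  expect_equal(s$category[["FS"]], 25)
  expect_equal(s$category[["SSD"]] + s$category[["SSA"]], 2)
  expect_equal(sum(s$impact), nrow(t3))
  expect_equal(sum(s$by_chromosome), nrow(t3))
  # high-impact indels concentrate on chromosomes 19 and 20 in this table
  expect_equal(unname(s$by_chromosome["High", "chr20"]), 5)

  empty <- impact_summary(t3[0, ])
  expect_true(all(empty$impact == 0) && all(empty$category == 0))
})

test_that("classify_indels appends one category per row and a GFF3 model reads back", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tID=tx1",
               "chr1\tsrc\tCDS\t301\t400\t.\t+\t1\tID=tx1"), gff)
  model <- read_transcript_gff3(gff)
  expect_equal(model$cds_intervals$start, c(101L, 301L))

  v <- rbind(make_variants(1, position = 150L, ref = "T", alt = "TG"),
             make_variants(1, position = 103L, ref = "A", alt = "ACAG"))
  out <- classify_indels(v, model)
  expect_equal(out$category, c("FS", "CI"))
  expect_equal(out$impact, c("High", "Moderate"))
  expect_equal(sum(out$impact %in% c("High", "Moderate", "Low")), nrow(out))
})
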