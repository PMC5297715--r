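test_that("marker calls follow the allele-fraction and depth thresholds", {
  expect_equal(classify_marker(20, 19), "homozygous")   # f = 0.95
  expect_equal(classify_marker(20, 10), "heterozygous") # f = 0.50
  expect_equal(classify_marker(20, 16), "ambiguous")    # f = 0.80
  expect_equal(classify_marker(8, 4), "ambiguous")      # het depth floor
  expect_equal(classify_marker(4, 4), "ambiguous")      # hom depth floor
  expect_equal(classify_marker(20, 5), "ambiguous")     # f = 0.25 < 0.30
  expect_equal(classify_marker(c(20, 10), c(20, 3)),
               c("homozygous", "heterozygous"))
  expect_error(classify_marker(0, 0), "uncovered")
  expect_error(classify_marker(10, 11), "exceeds depth")
})

test_that("map construction keeps deep autosomal sites, sorted and deduplicated", {
  sites <- data.frame(
    chromosome = c("chrX", "chr2", "chr1", "chr1", "chr1"),
    position = c(100L, 500L, 900L, 300L, 300L),
    depth = c(50L, 30L, 25L, 19L, 40L),
    variant_reads = c(50L, 15L, 25L, 9L, 39L))
  map <- build_marker_map(sites)
  expect_equal(map$chromosome, c("chr1", "chr1", "chr2"))
  expect_equal(map$position, c(300L, 900L, 500L))
  # duplicate chr1:300 collapses to the deeper record (depth 40 beats 19,
  # which would anyway fail the 20x floor)
  expect_equal(map$depth[1], 40L)
  expect_equal(map$call, c("homozygous", "homozygous", "heterozygous"))

  only_x <- build_marker_map(sites[sites$chromosome == "chrX", ])
  expect_equal(nrow(only_x), 0)
})

test_that("window qualification enforces the het and gap constraints", {
  p <- roh_params()
  # 600 all-homozygous markers at 1 kb spacing: all 101 windows qualify
  map <- make_map(rep("homozygous", 600))
  w <- scan_windows(map, p)
  expect_equal(nrow(w), 101)
  expect_true(all(w$qualified))

  # three heterozygous markers in every window: none qualify
  calls <- rep("homozygous", 600)
  calls[c(300, 301, 302)] <- "heterozygous"
  w3 <- scan_windows(make_map(calls), p)
  expect_false(any(w3$qualified[w3$first_marker_index > 302 - 500 &
                                  w3$first_marker_index <= 300]))
  expect_equal(sum(w3$het_count == 3), sum(!w3$qualified))

  # ambiguous markers fill windows but never count as heterozygous
  calls_amb <- rep("homozygous", 600)
  calls_amb[c(300, 301, 302)] <- "ambiguous"
  expect_true(all(scan_windows(make_map(calls_amb), p)$qualified))

  # a 600 kb gap disqualifies every window containing it
  pos <- seq_len(600) * 1000L
  pos[301:600] <- pos[301:600] + 600000L
  wg <- scan_windows(make_map(rep("homozygous", 600), positions = pos), p)
  straddles <- wg$first_marker_index <= 300 & wg$last_marker_index >= 301
  expect_equal(!wg$qualified, straddles)

  # chromosomes shorter than the window yield no windows
  expect_equal(nrow(scan_windows(make_map(rep("homozygous", 499)), p)), 0)
})

test_that("qualified windows coalesce into >= 1 Mb regions without crossing breaks", {
  p <- roh_params(window_markers = 10, max_het_per_window = 0,
                  min_region_bp = 1000000)
  # 0.8 Mb qualified run: below the length floor, nothing emitted
  short_map <- make_map(rep("homozygous", 100),
                        positions = seq(1, by = 8000, length.out = 100))
  expect_equal(nrow(map_homozygosity_from_map(short_map, p)), 0)

  # 1.5 Mb run: one region spanning first to last marker
  long_map <- make_map(rep("homozygous", 100),
                       positions = seq(1, by = 15100, length.out = 100))
  regions <- map_homozygosity_from_map(long_map, p)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$start_bp, 1L)
  expect_equal(regions$end_bp, long_map$position[100])
  expect_equal(regions$n_markers, 100L)

  # two qualified runs split by a heterozygous block stay two regions
  calls <- rep("homozygous", 300)
  calls[140:160] <- "heterozygous"
  split_map <- make_map(calls, positions = seq_len(300) * 12000L)
  regions2 <- map_homozygosity_from_map(split_map, p)
  expect_equal(nrow(regions2), 2)
  expect_true(regions2$end_bp[1] < split_map$position[160])
  expect_true(regions2$start_bp[2] > split_map$position[140])
  expect_true(all(regions2$length_bp >= p$min_region_bp))
})

test_that("the incremental scan matches the enumerating reference scan", {
  params_grid <- list(roh_params(window_markers = 25),
                      roh_params(window_markers = 25, max_het_per_window = 0),
                      roh_params(window_markers = 1))
  for (p in params_grid) {
    for (seed in 1:6) {
      map <- random_call_map(400, het_rate = 0.3, seed = seed,
                             big_gap_rate = 0.002)
      a <- scan_windows(map, p)
      b <- oracle_scan(map, p)
      expect_equal(a, b)
    }
  }
  # multi-chromosome map
  m1 <- random_call_map(120, 0.2, seed = 99)
  m2 <- random_call_map(80, 0.2, seed = 100)
  m2$chromosome <- "chr2"
  both <- structure(rbind(m1, m2), class = c("spex_marker_map", "data.frame"))
  p <- roh_params(window_markers = 50)
  expect_equal(scan_windows(both, p), oracle_scan(both, p))
  # degenerate one-marker windows: qualification is the het rule only
  p1 <- roh_params(window_markers = 1, max_het_per_window = 0)
  w1 <- scan_windows(m1, p1)
  expect_equal(w1$qualified, m1$call != "heterozygous")
})

test_that("loosening window constraints never removes qualified windows", {
  for (seed in 1:4) {
    map <- random_call_map(600, het_rate = 0.05, seed = seed,
                           big_gap_rate = 0.005)
    base <- roh_params(window_markers = 50, max_het_per_window = 1,
                       max_gap_bp = 300000)
    q0 <- scan_windows(map, base)$qualified
    for (p in list(roh_params(window_markers = 50, max_het_per_window = 3,
                              max_gap_bp = 300000),
                   roh_params(window_markers = 50, max_het_per_window = 1,
                              max_gap_bp = 700000))) {
      q1 <- scan_windows(map, p)$qualified
      expect_true(all(q1[q0]))
    }
    # raising the region length floor never adds regions
    w <- scan_windows(map, base)
    loose <- coalesce_windows(w, map, roh_params(window_markers = 50,
                                                 min_region_bp = 100000))
    tight <- coalesce_windows(w, map, roh_params(window_markers = 50,
                                                 min_region_bp = 400000))
    expect_lte(nrow(tight), nrow(loose))
    expect_true(all(tight$start_bp %in% loose$start_bp))
  }
})

test_that("emitted regions are disjoint and meet the length floor", {
  for (seed in 1:4) {
    map <- random_call_map(800, het_rate = 0.03, seed = 10 + seed)
    p <- roh_params(window_markers = 40, min_region_bp = 200000)
    regions <- coalesce_windows(scan_windows(map, p), map, p)
    expect_true(all(regions$length_bp >= p$min_region_bp))
    if (nrow(regions) > 1) {
      expect_true(all(regions$start_bp[-1] > regions$end_bp[-nrow(regions)]))
    }
  }
})

test_that("a planted homozygous stretch is recovered with tight boundaries", {
  plant <- data.frame(chromosome = "chr1", start = 4e6, end = 7e6)
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed,
                      genome = data.frame(chromosome = "chr1",
                                          length_bp = 12e6),
                      marker_spacing_bp = 5000, mean_depth = 30,
                      het_truth_rate = 1, roh_plants = plant)
    sim <- generate_marker_map(cfg)
    regions <- map_homozygosity(sim$markers)
    expect_equal(nrow(regions), 1)
    inside <- sim$markers$position >= plant$start &
      sim$markers$position <= plant$end
    # region covers every plant marker and leaks at most 5 markers per side
    expect_lte(regions$start_bp, min(sim$markers$position[inside]))
    expect_gte(regions$end_bp, max(sim$markers$position[inside]))
    expect_lte(sum(sim$markers$position < plant$start &
                     sim$markers$position >= regions$start_bp), 5)
    expect_lte(sum(sim$markers$position > plant$end &
                     sim$markers$position <= regions$end_bp), 5)
  }
})

test_that("heterozygous contamination obeys the two-per-window allowance", {
  # hom markers at 4 kb spacing; het contaminants on a 250-marker lattice
  # put at most 2 in any 500-marker window: the stretch survives
  calls <- rep("homozygous", 2000)
  calls[seq(125, 2000, by = 250)] <- "heterozygous"
  map <- make_map(calls, positions = seq_len(2000) * 4000L)
  expect_equal(nrow(map_homozygosity_from_map(map, roh_params())), 1)

  # 5 contaminants per window (every 100 markers): nothing qualifies
  calls5 <- rep("homozygous", 2000)
  calls5[seq(50, 2000, by = 100)] <- "heterozygous"
  map5 <- make_map(calls5, positions = seq_len(2000) * 4000L)
  expect_equal(nrow(map_homozygosity_from_map(map5, roh_params())), 0)

  # an all-heterozygous map yields no regions at all
  het_map <- make_map(rep("heterozygous", 1200))
  expect_equal(nrow(map_homozygosity_from_map(het_map, roh_params())), 0)
})
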