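#' Parameters for exome homozygosity mapping
#'
#' Defaults reproduce the study's mapping rules: autosomal markers with at
#' least 20-fold coverage form the map; a marker is called homozygous when
#' >= 95% of its reads carry one allele (at >= 5-fold), heterozygous when
#' 30--70% of reads carry the variant allele (at >= 10-fold), and
#' ambiguous otherwise; windows of 500 markers qualify when they contain
#' at most 2 heterozygous markers and no adjacent-marker gap above 500 kb;
#' qualified windows coalesce into homozygous regions of at least 1 Mb.
#'
#' Because the map-inclusion depth floor (20x) exceeds the per-call depth
#' floors (5x/10x), the latter are vacuous under defaults; they remain
#' active for non-default parameter sets.
#'
#' @param min_map_depth minimum depth for a site to enter the map.
#' @param hom_min_fraction,hom_min_depth homozygous call thresholds.
#' @param het_lo,het_hi,het_min_depth heterozygous call thresholds.
#' @param window_markers sliding-window size, in markers.
#' @param max_het_per_window maximum heterozygous markers per qualified
#'   window.
#' @param max_gap_bp maximum adjacent-marker gap inside a qualified window.
#' @param min_region_bp minimum emitted region length.
#' @return an object of class `spex_roh_params`.
#' @export
roh_params <- function(min_map_depth = 20L, hom_min_fraction = 0.95,
                       hom_min_depth = 5L, het_lo = 0.30, het_hi = 0.70,
                       het_min_depth = 10L, window_markers = 500L,
                       max_het_per_window = 2L, max_gap_bp = 500000L,
                       min_region_bp = 1000000L) {
  stopifnot(het_lo > 0, het_lo < het_hi, het_hi < hom_min_fraction,
            hom_min_fraction <= 1, is_count(window_markers),
            window_markers >= 1, max_het_per_window >= 0, max_gap_bp > 0,
            min_region_bp >= 0)
  structure(list(min_map_depth = as.integer(min_map_depth),
                 hom_min_fraction = hom_min_fraction,
                 hom_min_depth = as.integer(hom_min_depth),
                 het_lo = het_lo, het_hi = het_hi,
                 het_min_depth = as.integer(het_min_depth),
                 window_markers = as.integer(window_markers),
                 max_het_per_window = as.integer(max_het_per_window),
                 max_gap_bp = as.integer(max_gap_bp),
                 min_region_bp = as.integer(min_region_bp)),
            class = "spex_roh_params")
}

#' Classify a marker as homozygous, heterozygous or ambiguous
#'
#' With variant-allele fraction `f = variant_reads / depth`: homozygous
#' when `f >= hom_min_fraction` at `depth >= hom_min_depth`; heterozygous
#' when `het_lo <= f <= het_hi` at `depth >= het_min_depth`; everything
#' else (including `f` in the 70--95% band and depth-floor failures) is
#' ambiguous.
#'
#' @param depth,variant_reads integer vectors, `variant_reads <= depth`,
#'   `depth > 0`.
#' @param params [roh_params()].
#' @return character vector over `homozygous`, `heterozygous`,
#'   `ambiguous`.
#' @examples
#' classify_marker(c(20, 20, 20, 8), c(19, 10, 16, 4))
#' @export
classify_marker <- function(depth, variant_reads, params = roh_params()) {
  depth <- as.numeric(depth)
  variant_reads <- as.numeric(variant_reads)
  if (any(is.na(depth)) || any(depth == 0)) {
    stop("uncovered site: depth must be > 0", call. = FALSE)
  }
  if (any(variant_reads > depth)) {
    stop("variant_reads exceeds depth", call. = FALSE)
  }
  f <- variant_reads / depth
  out <- rep("ambiguous", length(f))
  out[f >= params$hom_min_fraction & depth >= params$hom_min_depth] <-
    "homozygous"
  out[f >= params$het_lo & f <= params$het_hi &
        depth >= params$het_min_depth] <- "heterozygous"
  out
}

#' Build the genetic marker map
#'
#' Retains autosomal sites with `depth >= min_map_depth`, sorts them by
#' chromosome and position, collapses duplicate positions to the deeper
#' record, and attaches the [classify_marker()] call.
#'
#' @param sites data.frame with `chromosome`, `position`, `depth`,
#'   `variant_reads` (e.g. from [read_marker_table()] or
#'   [generate_marker_map()]).
#' @param params [roh_params()].
#' @return the filtered, sorted map with a `call` column; class
#'   `spex_marker_map`.
#' @export
build_marker_map <- function(sites, params = roh_params()) {
  stopifnot(all(c("chromosome", "position", "depth", "variant_reads") %in%
                  names(sites)))
  sites$chromosome <- if (nrow(sites)) normalize_chromosome(sites$chromosome) else character(0)
  keep <- sites$chromosome %in% AUTOSOMES & sites$depth >= params$min_map_depth
  map <- sites[keep, c("chromosome", "position", "depth", "variant_reads"),
               drop = FALSE]
  o <- order(chromosome_rank(map$chromosome), map$position, -map$depth)
  map <- map[o, , drop = FALSE]
  dup <- duplicated(paste(map$chromosome, map$position))
  map <- map[!dup, , drop = FALSE]
  map$call <- if (nrow(map)) {
    classify_marker(map$depth, map$variant_reads, params)
  } else {
    character(0)
  }
  rownames(map) <- NULL
  class(map) <- c("spex_marker_map", "data.frame")
  map
}

#' Slide qualification windows over a marker map
#'
#' Windows of `window_markers` markers advance one marker at a time within
#' each chromosome (never straddling chromosomes). A window qualifies iff
#' it contains at most `max_het_per_window` heterozygous markers and every
#' adjacent-marker gap inside it is at most `max_gap_bp`. Ambiguous
#' markers occupy window slots and participate in the gap chain but never
#' count as heterozygous. Chromosomes with fewer markers than the window
#' size yield no windows.
#'
#' @param map a map from [build_marker_map()].
#' @param params [roh_params()].
#' @return data.frame of windows: `chromosome`, `first_marker_index`,
#'   `last_marker_index` (1-based indices into the per-chromosome marker
#'   list), `qualified`, `het_count`, `max_internal_gap_bp`.
#' @export
scan_windows <- function(map, params = roh_params()) {
  w <- params$window_markers
  out <- lapply(split(seq_len(nrow(map)), factor(map$chromosome,
                                                 unique(map$chromosome))),
                function(idx) {
    n <- length(idx)
    if (n < w) return(NULL)
    pos <- map$position[idx]
    het <- map$call[idx] == "heterozygous"
    nwin <- n - w + 1L
    cumhet <- c(0L, cumsum(het))
    het_count <- cumhet[seq_len(nwin) + w] - cumhet[seq_len(nwin)]
    if (w > 1L) {
      gaps <- diff(pos)
      bad <- gaps > params$max_gap_bp
      cumbad <- c(0L, cumsum(bad))
      bad_count <- cumbad[seq_len(nwin) + w - 1L] - cumbad[seq_len(nwin)]
      max_gap <- running_max(gaps, w - 1L)
    } else {
      bad_count <- integer(nwin)
      max_gap <- rep(NA_integer_, nwin)
    }
    data.frame(chromosome = map$chromosome[idx[1]],
               first_marker_index = seq_len(nwin),
               last_marker_index = seq_len(nwin) + w - 1L,
               qualified = het_count <= params$max_het_per_window &
                 bad_count == 0L,
               het_count = as.integer(het_count),
               max_internal_gap_bp = max_gap,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chromosome = character(0),
                      first_marker_index = integer(0),
                      last_marker_index = integer(0), qualified = logical(0),
                      het_count = integer(0),
                      max_internal_gap_bp = integer(0))
  }
  rownames(out) <- NULL
  out
}

# max over every length-k run of x (k >= 1), via a doubling trick
running_max <- function(x, k) {
  m <- x
  span <- 1L
  while (span < k) {
    step <- min(span, k - span)
    n <- length(m) - step
    m <- pmax(m[seq_len(n)], m[seq_len(n) + step])
    span <- span + step
  }
  m
}

#' Reference window scan by full enumeration
#'
#' Re-derives every window's qualification by explicit iteration — each
#' window's heterozygote count and gap chain are recomputed from scratch
#' with no incremental bookkeeping. Used as the independent check on
#' [scan_windows()]; intended for small maps.
#'
#' @inheritParams scan_windows
#' @return same shape as [scan_windows()].
#' @export
oracle_scan <- function(map, params = roh_params()) {
  w <- params$window_markers
  rows <- list()
  for (chrom in unique(map$chromosome)) {
    idx <- which(map$chromosome == chrom)
    n <- length(idx)
    if (n < w) next
    pos <- map$position[idx]
    call <- map$call[idx]
    for (i in seq_len(n - w + 1L)) {
      sel <- i:(i + w - 1L)
      hets <- sum(call[sel] == "heterozygous")
      gaps <- if (w > 1L) diff(pos[sel]) else integer(0)
      ok_gap <- all(gaps <= params$max_gap_bp)
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chrom, first_marker_index = i,
        last_marker_index = i + w - 1L,
        qualified = hets <= params$max_het_per_window && ok_gap,
        het_count = hets,
        max_internal_gap_bp = if (w > 1L) max(gaps) else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chromosome = character(0),
                      first_marker_index = integer(0),
                      last_marker_index = integer(0), qualified = logical(0),
                      het_count = integer(0),
                      max_internal_gap_bp = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coalesce qualified windows into homozygous regions
#'
#' Overlapping or marker-adjacent qualified windows on one chromosome
#' merge into maximal runs; merging never crosses a disqualified stretch.
#' Each run becomes a region spanning its first to last marker position
#' (1-based inclusive); runs shorter than `min_region_bp` are discarded.
#'
#' @param windows output of [scan_windows()].
#' @param map the map the windows were computed on.
#' @param params [roh_params()].
#' @return data.frame of regions sorted by chromosome and start:
#'   `chromosome`, `start_bp`, `end_bp`, `length_bp`, `n_markers`,
#'   `n_het_markers`.
#' @export
coalesce_windows <- function(windows, map, params = roh_params()) {
  w <- params$window_markers
  empty <- data.frame(chromosome = character(0), start_bp = integer(0),
                      end_bp = integer(0), length_bp = integer(0),
                      n_markers = integer(0), n_het_markers = integer(0))
  q <- windows[windows$qualified, , drop = FALSE]
  if (nrow(q) == 0) return(empty)
  regions <- list()
  for (chrom in unique(q$chromosome)) {
    starts <- sort(q$first_marker_index[q$chromosome == chrom])
    # windows [s, s+w-1]: merge while marker ranges overlap or touch
    run_break <- which(diff(starts) > w)
    run_first <- starts[c(1L, run_break + 1L)]
    run_last <- starts[c(run_break, length(starts))]
    idx <- which(map$chromosome == chrom)
    pos <- map$position[idx]
    call <- map$call[idx]
    for (r in seq_along(run_first)) {
      m1 <- run_first[r]
      m2 <- run_last[r] + w - 1L
      start_bp <- pos[m1]
      end_bp <- pos[m2]
      regions[[length(regions) + 1L]] <- data.frame(
        chromosome = chrom, start_bp = start_bp, end_bp = end_bp,
        length_bp = end_bp - start_bp + 1L, n_markers = m2 - m1 + 1L,
        n_het_markers = sum(call[m1:m2] == "heterozygous"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, regions)
  out <- out[out$length_bp >= params$min_region_bp, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out <- out[order(chromosome_rank(out$chromosome), out$start_bp), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map homozygous regions from raw marker sites
#'
#' End-to-end composition: [build_marker_map()], [scan_windows()],
#' [coalesce_windows()].
#'
#' @inheritParams build_marker_map
#' @return region data.frame as from [coalesce_windows()].
#' @examples
#' sim <- generate_marker_map(sim_config(
#'   seed = 7, genome = data.frame(chromosome = "chr1", length_bp = 4e6),
#'   roh_plants = data.frame(chromosome = "chr1", start = 1e6, end = 3e6),
#'   het_truth_rate = 1))
#' map_homozygosity(sim$markers)
#' @export
map_homozygosity <- function(sites, params = roh_params()) {
  map <- build_marker_map(sites, params)
  coalesce_windows(scan_windows(map, params), map, params)
}
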