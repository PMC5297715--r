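#' Normalize chromosome names
#'
#' Maps the spellings found in annotation tables ("chr01", "01", "1", "X")
#' onto the canonical vocabulary `chr1..chr22`, `chrX`, `chrY`.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of canonical labels.
#' @examples
#' normalize_chromosome(c("chr01", "3", "chrX"))
#' @export
normalize_chromosome <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^chr", "", x, ignore.case = TRUE)
  x <- sub("^0+(?=.)", "", x, perl = TRUE)   # chr01 -> 1, keep "0" intact
  x <- toupper(x)
  out <- paste0("chr", x)
  bad <- !(out %in% CHROMOSOMES)
  if (any(bad)) {
    stop("unrecognized chromosome label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Normalize gene symbols
#'
#' Strips markdown emphasis and whitespace and upper-cases symbols so that
#' sets of genes coming from differently typeset tables compare equal
#' (`*CTNNB1*` == `CTNNB1` == `ctnnb1`).
#'
#' @param x character vector of gene symbols.
#' @return character vector of bare, upper-case symbols.
#' @export
normalize_gene <- function(x) {
  toupper(gsub("[*_[:space:]]", "", as.character(x)))
}

# sort order for chromosome labels: numeric autosomes, then X, Y
chromosome_rank <- function(x) {
  match(x, CHROMOSOMES)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
}
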