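#' Construct a fragment table
#'
#' A fragment is one sequenced duplex insert. Coordinates are 0-based
#' half-open throughout the package (BED-native): a fragment covers bases
#' `start .. end - 1` and has length `end - start`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector of 0-based start positions.
#' @param end Integer vector of exclusive end positions (`start < end`).
#' @param strand Strand of the nascent (first-in-pair) strand: `"+"`
#'   (Watson), `"-"` (Crick) or `"*"` for strandless assays such as
#'   MNase-seq.
#' @param mark Optional label carried with each fragment (e.g.
#'   `"parental"`, `"new"`, `"mnase"`); `NA` if absent.
#' @return A `data.frame` of class `espan_fragments` with columns
#'   `chrom`, `start`, `end`, `strand`, `mark`.
#' @examples
#' fragments("chrI", 100, 250, "+")
#' @export
fragments <- function(chrom, start, end, strand = "*", mark = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    mark = rep_len(as.character(mark), n),
    stringsAsFactors = FALSE
  )
  validate_fragments(df)
  class(df) <- c("espan_fragments", "data.frame")
  df
}

validate_fragments <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  bad <- which(!(df$start < df$end))
  if (length(bad) > 0) {
    stop("invalid fragment(s): start >= end at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (any(df$start < 0)) stop("fragment start must be >= 0")
  if (!all(df$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  invisible(df)
}

#' Fragment lengths and midpoints
#'
#' Length is `end - start` (half-open coordinates); the midpoint is
#' `floor((start + end) / 2)`, the base used for nucleosome assignment.
#'
#' @param frags A [fragments()] table.
#' @return An integer-valued vector, one element per fragment.
#' @export
fragment_lengths <- function(frags) frags$end - frags$start

#' @rdname fragment_lengths
#' @export
fragment_midpoints <- function(frags) floor((frags$start + frags$end) / 2)

#' Coerce a data.frame to a validated fragment table
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `strand`
#'   and optionally `mark`.
#' @return An [fragments()] table.
#' @export
as_fragments <- function(df) {
  validate_fragments(df)
  if (!"mark" %in% names(df)) df$mark <- NA_character_
  class(df) <- c("espan_fragments", "data.frame")
  rownames(df) <- NULL
  df
}

#' @export
print.espan_fragments <- function(x, ...) {
  cat(sprintf("<espan_fragments> %d fragments on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0) {
    cat(sprintf("  lengths %d-%d bp; strands: %s\n",
                min(fragment_lengths(x)), max(fragment_lengths(x)),
                paste(names(table(x$strand)), collapse = "/")))
  }
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
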