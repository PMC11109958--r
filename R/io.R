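#' Read fragments from a BED-like table or an alignment file
#'
#' The table format is BED6 with the name column carrying the optional
#' mark label: `chrom  start  end  mark  score  strand` (tab-separated,
#' 0-based half-open; `.` means no mark; score is ignored; strand and
#' later columns may be absent, in which case the fragment is
#' strandless). Malformed lines are rejected with their line numbers.
#'
#' Alignment input (SAM/BAM) keeps only properly paired reads and takes
#' one fragment per pair, spanning the outer ends of the insert; the
#' fragment strand is the strand of the first-in-pair read, which in
#' strand-preserving single-strand libraries carries the nascent-strand
#' identity.
#'
#' @param path Input file.
#' @param format `"table"` (default, BED-like) or `"sam"`.
#' @param dedup Remove duplicate fragments (identical chrom, start, end,
#'   strand)? Default `FALSE`; whether the original analyses
#'   deduplicated is not documented, so the flag is exposed and off.
#' @return An [fragments()] table.
#' @export
read_fragments <- function(path, format = c("table", "sam"),
                           dedup = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  frags <- switch(format,
                  table = read_fragments_table(path),
                  sam = read_fragments_sam(path))
  if (dedup) {
    key <- paste(frags$chrom, frags$start, frags$end, frags$strand)
    frags <- as_fragments(frags[!duplicated(key), , drop = FALSE])
  }
  frags
}

read_fragments_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(fragments(character(0), numeric(0), numeric(0) + 1))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop("malformed line(s) (fewer than 3 fields): line ",
         paste(which(nf < 3), collapse = ", "))
  }
  chrom <- vapply(parts, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("non-numeric coordinates: line ", paste(bad, collapse = ", "))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    stop("invalid interval (start >= end or start < 0): line ",
         paste(bad, collapse = ", "))
  }
  mark <- ifelse(nf >= 4, vapply(parts, function(p)
    if (length(p) >= 4) p[4] else ".", ""), ".")
  mark[mark == "."] <- NA_character_
  strand <- ifelse(nf >= 6, vapply(parts, function(p)
    if (length(p) >= 6) p[6] else "*", ""), "*")
  bad <- which(!strand %in% c("+", "-", "*", "."))
  if (length(bad) > 0) {
    stop("invalid strand: line ", paste(bad, collapse = ", "))
  }
  strand[strand == "."] <- "*"
  as_fragments(data.frame(chrom = chrom, start = start, end = end,
                          strand = strand, mark = mark,
                          stringsAsFactors = FALSE))
}

read_fragments_sam <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE,
                                 isFirstMateRead = TRUE)
  p <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "pos", "mpos", "isize", "strand"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$isize) & x$isize != 0
  rname <- as.character(x$rname)[keep]
  pos <- x$pos[keep]; mpos <- x$mpos[keep]
  isize <- x$isize[keep]
  strand <- as.character(x$strand)[keep]
  start <- pmin(pos, mpos) - 1L            # SAM pos is 1-based
  as_fragments(data.frame(chrom = rname, start = start,
                          end = start + abs(isize), strand = strand,
                          mark = NA_character_,
                          stringsAsFactors = FALSE))
}

#' Write fragments as a BED-like table
#'
#' Inverse of `read_fragments(format = "table")`: round-trips exactly.
#'
#' @param frags A [fragments()] table.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fragments <- function(frags, path) {
  validate_fragments(frags)
  mark <- ifelse(is.na(frags$mark), ".", frags$mark)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", frags$chrom,
                     as.integer(frags$start), as.integer(frags$end),
                     mark, frags$strand), path)
  invisible(path)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a bias matrix or profile as TSV
#'
#' Matrices get a header of nucleosome positions (-10..-1, +1..+10) and
#' one row per origin in genomic order, values at full precision so
#' `read_matrix(write_matrix(m)) == m`; missing cells are written `NA`.
#' Profiles are written with their own columns.
#'
#' @param x A [bias_matrix()], [average_bias_profile()] result, or any
#'   data.frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(x, path) {
  if (inherits(x, "bias_matrix")) {
    header <- paste(c("origin", colnames(x)), collapse = "\t")
    rows <- vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], fmt_num(x[i, ])), collapse = "\t")
    }, "")
    writeLines(c(header, rows), path)
  } else {
    df <- as.data.frame(x)
    num <- vapply(df, is.numeric, logical(1))
    out <- df
    out[num] <- lapply(df[num], fmt_num)
    writeLines(c(paste(names(out), collapse = "\t"),
                 do.call(paste, c(out, sep = "\t"))), path)
  }
  invisible(path)
}

#' Read a bias matrix written by [write_matrix()]
#'
#' @param path TSV file with an `origin` column followed by nucleosome
#'   positions.
#' @return A `bias_matrix`.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "origin") stop("expected an 'origin' header column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$origin)
  storage.mode(m) <- "double"
  structure(m, pseudocount = NA_real_,
            class = c("bias_matrix", class(m)))
}

#' Write a coverage track as bedGraph
#'
#' 0-based half-open intervals; runs of equal coverage are emitted as
#' single lines (maximal runs, so adjacent lines always differ in
#' value); zero-coverage runs are omitted as bedGraph convention.
#'
#' @param track A [coverage_track()].
#' @param path Output file.
#' @param keep_zero Also write zero-coverage runs? Default `FALSE`.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, keep_zero = FALSE) {
  stopifnot(inherits(track, "coverage_track"))
  lines <- character(0)
  for (chrom in names(track$cov)) {
    r <- track$cov[[chrom]]
    rl <- S4Vectors::runLength(r)
    rv <- S4Vectors::runValue(r)
    ends <- cumsum(rl)
    starts <- ends - rl            # 0-based
    keep <- if (keep_zero) rep(TRUE, length(rv)) else rv != 0
    if (any(keep)) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s", chrom,
                                as.integer(starts[keep]),
                                as.integer(ends[keep]),
                                fmt_num(as.numeric(rv[keep]))))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Bases not covered by any interval get value 0. Chromosome lengths
#' default to the largest end seen per chromosome.
#'
#' @param path bedGraph file (0-based half-open intervals).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines) == 0 && is.null(chrom_lengths)) {
    stop("empty bedGraph and no chromosome lengths given")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4)) {
    stop("malformed bedGraph line: ",
         paste(which(lengths(parts) < 4), collapse = ", "))
  }
  chrom <- vapply(parts, `[`, "", 1L)
  start <- as.numeric(vapply(parts, `[`, "", 2L))
  end <- as.numeric(vapply(parts, `[`, "", 3L))
  value <- as.numeric(vapply(parts, `[`, "", 4L))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(end, chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  cov <- S4Vectors::SimpleList(lapply(names(chrom_lengths), function(ch) {
    r <- S4Vectors::Rle(0, chrom_lengths[[ch]])
    sel <- chrom == ch
    if (any(sel)) {
      for (i in which(sel)) {
        idx <- (start[i] + 1):end[i]
        r[idx] <- value[i]
      }
    }
    r
  }))
  names(cov) <- names(chrom_lengths)
  structure(list(cov = cov, chrom_lengths = chrom_lengths),
            class = "coverage_track")
}
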