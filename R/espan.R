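positions_20 <- c(-10:-1, 1:10)

#' Filter fragments by insert size
#'
#' Keeps fragments whose length (`end - start`) lies in the inclusive
#' window `[min_len, max_len]`; input order is preserved. The
#' mononucleosome window for eSPAN data is 120-170 bp; MNase-seq
#' occupancy uses 149-170 bp.
#'
#' @param frags A [fragments()] table.
#' @param min_len,max_len Inclusive bounds in bp.
#' @return The surviving fragments (possibly zero rows).
#' @export
filter_fragments <- function(frags, min_len = 120, max_len = 170) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  len <- fragment_lengths(frags)
  as_fragments(frags[len >= min_len & len <= max_len, , drop = FALSE])
}

#' Count fragments into origin-anchored nucleosome bins by strand
#'
#' Each fragment is assigned to the unique nucleosome interval containing
#' its midpoint (`floor((start + end) / 2)`, half-open intervals, so ties
#' are impossible); fragments whose midpoint falls in no interval are
#' ignored. Counts are accumulated per (origin, nucleosome position,
#' strand).
#'
#' @param frags A [fragments()] table with strands `+` (Watson) or `-`
#'   (Crick).
#' @param nucmap Nucleosome map: data.frame with columns `origin_id`,
#'   `chrom`, `index` (-10..-1, +1..+10), `start`, `end` (0-based
#'   half-open), e.g. `fixture$origin_nucs` or [read_nucmap()] output.
#' @return A `counts_tensor`: integer array
#'   `[origin, position, strand]` with dimnames; origins ordered by
#'   genomic coordinate.
#' @export
count_by_nucleosome <- function(frags, nucmap) {
  need <- c("origin_id", "chrom", "index", "start", "end")
  stopifnot(all(need %in% names(nucmap)))
  if (!all(frags$strand %in% c("+", "-"))) {
    stop("eSPAN fragments must be stranded (+/-)")
  }
  gr_nuc <- GenomicRanges::GRanges(
    nucmap$chrom,
    IRanges::IRanges(start = nucmap$start + 1L, end = nucmap$end))
  self <- GenomicRanges::findOverlaps(gr_nuc, gr_nuc)
  if (length(self) > length(gr_nuc)) {
    stop("nucleosome intervals overlap; fragment assignment is ambiguous")
  }

  # origins ordered by genomic coordinate (chrom, then leftmost interval)
  ostart <- tapply(nucmap$start, nucmap$origin_id, min)
  ochrom <- tapply(nucmap$chrom, nucmap$origin_id, `[`, 1L)
  oid <- names(ostart)[order(unlist(ochrom), unlist(ostart))]

  counts <- array(0L,
                  dim = c(length(oid), length(positions_20), 2L),
                  dimnames = list(origin = oid,
                                  position = as.character(positions_20),
                                  strand = c("W", "C")))
  if (nrow(frags) > 0) {
    mid <- fragment_midpoints(frags)
    gr_mid <- GenomicRanges::GRanges(
      frags$chrom, IRanges::IRanges(start = mid + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(gr_mid, gr_nuc)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (length(qi) > 0) {
      o <- match(as.character(nucmap$origin_id[si]), oid)
      p <- match(as.character(nucmap$index[si]),
                 as.character(positions_20))
      s <- ifelse(frags$strand[qi] == "+", 1L, 2L)
      nO <- length(oid); nP <- length(positions_20)
      key <- o + (p - 1L) * nO + (s - 1L) * nO * nP  # column-major cell
      counts[] <- tabulate(key, nbins = length(counts))
    }
  }
  structure(counts, class = c("counts_tensor", class(counts)))
}

#' Per-origin log2(Watson/Crick) bias matrix
#'
#' Each cell is `log2((W + pseudocount) / (C + pseudocount))` for the
#' Watson and Crick counts of one (origin, nucleosome position) cell.
#' With `pseudocount = 0`, cells where either strand count is zero are
#' undefined and marked `NA` (a ratio of 0 or infinity has no finite
#' log); with a positive pseudocount every cell is finite and a
#' zero/zero cell is exactly 0. The matrix is antisymmetric under
#' swapping strand labels.
#'
#' @param counts A [count_by_nucleosome()] tensor.
#' @param pseudocount Non-negative count added to both strands
#'   (default 1, which keeps low-coverage positions defined).
#' @return A `bias_matrix`: numeric matrix origins x positions with the
#'   pseudocount stored as an attribute.
#' @export
bias_matrix <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "counts_tensor"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  w <- counts[, , "W", drop = FALSE] + pseudocount
  c_ <- counts[, , "C", drop = FALSE] + pseudocount
  dim(w) <- dim(c_) <- dim(counts)[1:2]
  # difference of logs, not log of quotient: swapping W and C then
  # negates every finite cell bit-exactly
  m <- log2(w) - log2(c_)
  m[!is.finite(m)] <- NA_real_
  dimnames(m) <- list(dimnames(counts)[[1]], dimnames(counts)[[2]])
  structure(m, pseudocount = pseudocount,
            class = c("bias_matrix", class(m)))
}

#' Position-averaged bias profile across origins
#'
#' Arithmetic mean of the per-origin bias at each nucleosome position,
#' over origins with a defined (non-missing) value there, with the
#' standard error of that mean and the number of origins used. A
#' position with no usable origin is reported with `mean = NA` and
#' `n = 0`, never silently as zero.
#'
#' @param matrix A [bias_matrix()].
#' @return A `bias_profile` data.frame: `position`, `mean`, `sem`, `n`.
#' @export
average_bias_profile <- function(matrix) {
  stopifnot(inherits(matrix, "bias_matrix"))
  if (nrow(matrix) < 1) stop("need at least one origin")
  pos <- as.integer(colnames(matrix))
  n <- colSums(!is.na(matrix))
  mu <- ifelse(n > 0, colMeans(matrix, na.rm = TRUE), NA_real_)
  sdv <- apply(matrix, 2, stats::sd, na.rm = TRUE)
  sem <- ifelse(n > 1, sdv / sqrt(n), NA_real_)
  structure(data.frame(position = pos, mean = unname(mu),
                       sem = unname(sem), n = unname(n)),
            class = c("bias_profile", "data.frame"))
}

#' Fold a bias profile onto a single lagging-strand axis
#'
#' Right-side positions are sign-flipped and merged with the matching
#' left-side positions by absolute index (an n-weighted mean), so that
#' under the package's strand convention a positive folded value means
#' lagging-strand enrichment at that nucleosome distance regardless of
#' side. The paper-style unfolded Watson/Crick profile is the primary
#' output; folding is a summary convenience.
#'
#' @param profile A [average_bias_profile()] result.
#' @return A data.frame `nucleosome` (1..10), `mean`, `sem`, `n`.
#' @export
fold_leading_lagging <- function(profile) {
  stopifnot(inherits(profile, "bias_profile"))
  ks <- sort(unique(abs(profile$position)))
  out <- lapply(ks, function(k) {
    l <- profile[profile$position == -k, ]
    r <- profile[profile$position == k, ]
    vals <- c(l$mean, -r$mean)
    ns <- c(l$n, r$n)
    sems <- c(l$sem, r$sem)
    use <- !is.na(vals) & ns > 0
    if (!any(use)) {
      return(data.frame(nucleosome = k, mean = NA_real_,
                        sem = NA_real_, n = 0L))
    }
    w <- ns[use] / sum(ns[use])
    data.frame(nucleosome = k,
               mean = sum(w * vals[use]),
               sem = sqrt(sum((w * sems[use])^2)),
               n = sum(ns[use]))
  })
  do.call(rbind, out)
}
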