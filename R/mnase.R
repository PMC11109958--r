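#' Per-base fragment coverage track
#'
#' Every base covered by a fragment's half-open `[start, end)` span
#' increments by one, so the total base coverage equals the sum of
#' fragment lengths. Backed by run-length encodings (one per
#' chromosome).
#'
#' @param frags A [fragments()] table.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp);
#'   a fragment outside its chromosome is an error.
#' @return A `coverage_track`: list with the per-chromosome `RleList`
#'   and `chrom_lengths`.
#' @export
coverage_track <- function(frags, chrom_lengths) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  unknown <- setdiff(unique(frags$chrom), names(chrom_lengths))
  if (length(unknown) > 0) {
    stop("fragments on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  }
  lim <- chrom_lengths[frags$chrom]
  if (any(frags$start < 0) || any(frags$end > lim)) {
    stop("fragment outside chromosome bounds")
  }
  gr <- GenomicRanges::GRanges(
    frags$chrom,
    IRanges::IRanges(start = frags$start + 1L, end = frags$end),
    seqlengths = chrom_lengths)
  structure(list(cov = GenomicRanges::coverage(gr),
                 chrom_lengths = chrom_lengths),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- sum(vapply(x$cov, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                             S4Vectors::runLength(r)), 0))
  cat(sprintf("<coverage_track> %d chromosome(s), total base coverage %g\n",
              length(x$cov), tot))
  invisible(x)
}

# per-base coverage over a 0-based window [from, to) on one chromosome
coverage_window <- function(track, chrom, from, to) {
  r <- track$cov[[chrom]]
  if (is.null(r)) stop("unknown chromosome: ", chrom)
  as.numeric(S4Vectors::window(r, start = from + 1L, end = to))
}

#' Standardize coverage in a window around an anchor
#'
#' Extracts per-base coverage over `anchor - half_width .. anchor +
#' half_width` (inclusive, `2 * half_width + 1` values) and standardizes
#' it to mean 0 and unit variance using the population (n) convention --
#' the window is the full population of positions. Minus-strand anchors
#' are reversed so that positive offsets always point downstream. A
#' window with zero variance carries no positional signal and is
#' returned as all-`NA` (excluded from metaprofile averaging).
#'
#' @param track A [coverage_track()].
#' @param chrom,pos Anchor chromosome and 0-based position.
#' @param strand `"+"` or `"-"` (`"*"` treated as `"+"`).
#' @param half_width Window half-width in bp.
#' @return Numeric vector of length `2 * half_width + 1`, named by
#'   offset `-half_width .. half_width`.
#' @export
standardize_region <- function(track, chrom, pos, strand = "+",
                               half_width = 500) {
  stopifnot(inherits(track, "coverage_track"), half_width >= 1)
  len <- track$chrom_lengths[chrom]
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  if (pos - half_width < 0 || pos + half_width >= len) {
    stop("window extends beyond chromosome bounds")
  }
  x <- coverage_window(track, chrom, pos - half_width,
                       pos + half_width + 1L)
  if (strand == "-") x <- rev(x)
  mu <- mean(x)
  sdv <- sqrt(mean((x - mu)^2))
  out <- if (sdv == 0) rep(NA_real_, length(x)) else (x - mu) / sdv
  names(out) <- as.character(-half_width:half_width)
  out
}

#' Average standardized-occupancy metaprofile over anchors
#'
#' Standardizes each anchor's window with [standardize_region()] and
#' averages positionwise over the usable anchors (equal weight per
#' anchor; constant-coverage windows are dropped). This is the standard
#' nucleosome-occupancy metaprofile around TSS or replication origins.
#'
#' @param track A [coverage_track()].
#' @param anchors data.frame with columns `chrom`, `pos` and optionally
#'   `strand` (default `+`).
#' @param half_width Window half-width in bp (default 500).
#' @return A `meta_profile` data.frame: `offset` (bp, -half_width..
#'   half_width), `mean` standardized coverage, `n` usable anchors.
#' @export
metaprofile <- function(track, anchors, half_width = 500) {
  stopifnot(all(c("chrom", "pos") %in% names(anchors)),
            nrow(anchors) >= 1)
  strand <- if ("strand" %in% names(anchors)) anchors$strand else
    rep("+", nrow(anchors))
  mat <- vapply(seq_len(nrow(anchors)), function(i) {
    standardize_region(track, anchors$chrom[i], anchors$pos[i],
                       strand[i], half_width)
  }, numeric(2 * half_width + 1))
  usable <- colSums(is.na(mat)) == 0
  if (!any(usable)) stop("no usable anchors (all windows constant)")
  structure(data.frame(offset = -half_width:half_width,
                       mean = rowMeans(mat[, usable, drop = FALSE]),
                       n = sum(usable)),
            class = c("meta_profile", "data.frame"))
}

#' Relative mononucleosome / undigested chromatin ratio from band
#' intensities
#'
#' For each strain, the ratio of the mononucleosome band intensity to
#' the undigested-chromatin band intensity, reported relative to a
#' designated reference strain (reference = 1.0). Intensities come from
#' gel densitometry and must be positive.
#'
#' @param bands data.frame with columns `strain`, `band` (values
#'   `"mono"` and `"undigested"`) and `intensity`.
#' @param reference Name of the reference strain.
#' @return data.frame `strain`, `ratio` (mono/undigested), `relative`
#'   (ratio / reference ratio).
#' @export
mono_undigested_ratio <- function(bands, reference = "WT") {
  stopifnot(all(c("strain", "band", "intensity") %in% names(bands)))
  if (any(bands$intensity <= 0)) {
    stop("band intensities must be positive")
  }
  strains <- unique(bands$strain)
  ratio <- vapply(strains, function(s) {
    m <- bands$intensity[bands$strain == s & bands$band == "mono"]
    u <- bands$intensity[bands$strain == s & bands$band == "undigested"]
    if (length(m) != 1 || length(u) != 1) {
      stop("strain ", s, " needs exactly one mono and one undigested band")
    }
    m / u
  }, numeric(1))
  if (!reference %in% strains) {
    stop("reference strain not in table: ", reference)
  }
  data.frame(strain = strains, ratio = unname(ratio),
             relative = unname(ratio / ratio[strains == reference]),
             stringsAsFactors = FALSE)
}

#' Locate metaprofile peaks near expected offsets
#'
#' Nucleosomal coverage peaks are flat-topped (a positioning kernel
#' convolved with the ~150 bp fragment footprint), so a raw argmax
#' wanders on the plateau; a light running-mean smooth before the argmax
#' localizes the peak centre. For each expected offset the argmax of the
#' smoothed profile within `+/- window` bp is returned.
#'
#' @param profile A [metaprofile()] result.
#' @param expected Numeric vector of offsets (bp) near which to search.
#' @param window Search half-width around each expected offset (bp).
#' @param smooth Running-mean width in bp (odd; default 41).
#' @return data.frame `expected`, `peak` (located offset), `error`
#'   (peak - expected).
#' @export
profile_peaks <- function(profile, expected, window = 82, smooth = 41) {
  stopifnot(inherits(profile, "meta_profile"), smooth %% 2 == 1)
  sm <- stats::filter(profile$mean, rep(1 / smooth, smooth))
  peak <- vapply(expected, function(o) {
    sel <- which(abs(profile$offset - o) <= window & !is.na(sm))
    if (length(sel) == 0) return(NA_real_)
    profile$offset[sel][which.max(sm[sel])]
  }, numeric(1))
  data.frame(expected = expected, peak = peak, error = peak - expected)
}
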