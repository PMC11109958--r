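#' Build a synthetic genome fixture with origins, genes and positioned
#' nucleosomes
#'
#' Lays out a small two-chromosome genome: replication origins on `chrI`,
#' each flanked by a nucleosome-free region (NFR) and ten positioned
#' nucleosomes per side (indices -10..-1 and +1..+10, no position 0 -- the
#' origin itself sits in the NFR), and genes on `chrII`, each with an NFR
#' at the transcription start site followed by six positioned nucleosomes
#' (+1..+6) downstream on the gene's strand. Anchors are evenly spaced so
#' their nucleosome windows never overlap each other or a chromosome end.
#'
#' @param n_origins Number of replication origins.
#' @param n_genes Number of genes (TSS anchors).
#' @param chrom_length Length of each chromosome in bp.
#' @param spacing Nucleosome repeat length in bp (dyad-to-dyad). Default
#'   165 bp, a typical budding-yeast repeat.
#' @param nfr_width Width of the nucleosome-free region in bp.
#' @param seed Integer seed; gene strands are the only random element, so
#'   a fixed seed gives byte-identical output.
#' @return An object of class `genome_fixture`: a list with
#'   `chrom_lengths`, `origins` (chrom, origin_id, midpoint),
#'   `origin_nucs` (origin_id, chrom, index, dyad, start, end),
#'   `tss` (chrom, gene_id, pos, strand), `gene_nucs`
#'   (gene_id, chrom, index, dyad), plus the layout parameters.
#' @examples
#' gf <- make_genome(n_origins = 4, n_genes = 3, chrom_length = 60000)
#' gf
#' @export
make_genome <- function(n_origins, n_genes, chrom_length = 1e6,
                        spacing = 165, nfr_width = 140, seed = 1L) {
  stopifnot(n_origins >= 1, n_genes >= 0, chrom_length > 0,
            spacing >= 147, nfr_width >= 0)
  half_window <- nfr_width / 2 + 10 * spacing
  step <- chrom_length / (n_origins + 1)
  if (step <= 2 * half_window) {
    stop(sprintf(
      "chromosome of %d bp cannot hold %d origins with %.0f bp windows",
      chrom_length, n_origins, 2 * half_window))
  }
  mids <- round((seq_len(n_origins)) * step)
  if (any(mids - half_window < 0) || any(mids + half_window > chrom_length)) {
    stop("origin windows would overlap chromosome ends")
  }

  idx <- c(-10:-1, 1:10)
  # dyad of nucleosome k sits nfr/2 + (|k|-1/2)*spacing from the midpoint
  offs <- sign(idx) * (nfr_width / 2 + (abs(idx) - 0.5) * spacing)
  origin_nucs <- data.frame(
    origin_id = rep(seq_len(n_origins), each = length(idx)),
    chrom = "chrI",
    index = rep(idx, n_origins),
    dyad = rep(mids, each = length(idx)) + rep(offs, n_origins),
    stringsAsFactors = FALSE
  )
  origin_nucs$start <- origin_nucs$dyad - spacing / 2
  origin_nucs$end <- origin_nucs$dyad + spacing / 2
  # half-open integer bins, contiguous within each side
  origin_nucs$start <- floor(origin_nucs$start)
  origin_nucs$end <- floor(origin_nucs$end)
  origin_nucs$dyad <- round(origin_nucs$dyad)

  tss <- gene_nucs <- NULL
  if (n_genes > 0) {
    gene_half <- nfr_width / 2 + 6 * spacing
    gstep <- chrom_length / (n_genes + 1)
    if (gstep <= 2 * gene_half) {
      stop(sprintf(
        "chromosome of %d bp cannot hold %d genes with %.0f bp windows",
        chrom_length, n_genes, 2 * gene_half))
    }
    gpos <- round(seq_len(n_genes) * gstep)
    gstrand <- withr::with_seed(as.integer(seed), {
      c("+", "-")[stats::rbinom(n_genes, 1, 0.5) + 1]
    })
    tss <- data.frame(chrom = "chrII", gene_id = seq_len(n_genes),
                      pos = gpos, strand = gstrand,
                      stringsAsFactors = FALSE)
    goff <- nfr_width / 2 + (1:6 - 0.5) * spacing
    sgn <- ifelse(rep(gstrand, each = 6) == "+", 1, -1)
    gene_nucs <- data.frame(
      gene_id = rep(seq_len(n_genes), each = 6),
      chrom = "chrII",
      index = rep(1:6, n_genes),
      dyad = round(rep(gpos, each = 6) + sgn * rep(goff, n_genes)),
      stringsAsFactors = FALSE
    )
  }

  gf <- list(
    chrom_lengths = c(chrI = chrom_length, chrII = chrom_length),
    origins = data.frame(chrom = "chrI", origin_id = seq_len(n_origins),
                         midpoint = mids, stringsAsFactors = FALSE),
    origin_nucs = origin_nucs,
    tss = tss,
    gene_nucs = gene_nucs,
    spacing = spacing,
    nfr_width = nfr_width,
    seed = as.integer(seed)
  )
  class(gf) <- "genome_fixture"
  gf
}

#' @export
print.genome_fixture <- function(x, ...) {
  cat(sprintf(
    "<genome_fixture> %d origins (chrI), %d genes (chrII), %d bp each\n",
    nrow(x$origins), if (is.null(x$tss)) 0L else nrow(x$tss),
    unname(x$chrom_lengths[1])))
  cat(sprintf("  nucleosome spacing %g bp, NFR %g bp\n",
              x$spacing, x$nfr_width))
  invisible(x)
}

#' Write a genome fixture to BED and TSV files
#'
#' Emits `origins.bed` (origin midpoints as 1 bp intervals), `tss.bed`
#' (stranded TSS positions) and `nucmap.tsv` (the origin nucleosome map:
#' origin_id, chrom, index, start, end, dyad). Output is deterministic:
#' the same fixture always produces byte-identical files.
#'
#' @param fixture A [make_genome()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (named character vector).
#' @export
write_genome_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "genome_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(origins = file.path(dir, "origins.bed"),
             tss = file.path(dir, "tss.bed"),
             nucmap = file.path(dir, "nucmap.tsv"))
  o <- fixture$origins
  writeLines(sprintf("%s\t%d\t%d\tori%d\t0\t+", o$chrom, o$midpoint,
                     o$midpoint + 1L, o$origin_id), paths["origins"])
  if (!is.null(fixture$tss)) {
    t <- fixture$tss
    writeLines(sprintf("%s\t%d\t%d\tgene%d\t0\t%s", t$chrom, t$pos,
                       t$pos + 1L, t$gene_id, t$strand), paths["tss"])
  } else {
    writeLines(character(0), paths["tss"])
  }
  n <- fixture$origin_nucs
  lines <- c("origin_id\tchrom\tindex\tstart\tend\tdyad",
             sprintf("%d\t%s\t%d\t%d\t%d\t%d", n$origin_id, n$chrom,
                     n$index, n$start, n$end, n$dyad))
  writeLines(lines, paths["nucmap"])
  invisible(paths)
}

#' Read an origin nucleosome map written by [write_genome_fixture()]
#'
#' @param path Path to a `nucmap.tsv` file.
#' @return A data.frame with columns origin_id, chrom, index, start, end,
#'   dyad.
#' @export
read_nucmap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("origin_id", "chrom", "index", "start", "end")
  if (!all(need %in% names(df))) {
    stop("nucleosome map must have columns: ", paste(need, collapse = ", "))
  }
  df
}
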