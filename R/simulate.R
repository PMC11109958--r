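#' Genotype parameters for the eSPAN simulator
#'
#' `p_lagging` is the probability that a parental-mark fragment at any
#' origin-flanking nucleosome derives from the lagging nascent strand.
#' Under the package's strand convention (Watson = reference forward
#' strand; forks move outward from the origin) the lagging strand is
#' Watson at nucleosomes LEFT of the origin and Crick at nucleosomes
#' RIGHT of it, so a lagging-strand preference produces the
#' positive-left / negative-right log2(W/C) pattern.
#'
#' @param name Genotype label.
#' @param p_lagging Probability in the open interval (0, 1).
#' @param depth Signal fragments per origin side (>= 1).
#' @param frag_mean,frag_sd Fragment length distribution (bp), clipped to
#'   120-170 bp at simulation time.
#' @param background Fraction of emitted fragments placed uniformly on
#'   the chromosome with fair strand choice; must be < 1.
#' @param jitter_sd Standard deviation (bp) of fragment midpoints around
#'   the nucleosome dyad.
#' @param seed Integer seed for this genotype's RNG stream.
#' @return A list of class `genotype_params`.
#' @export
genotype_params <- function(name, p_lagging, depth,
                            frag_mean = 148, frag_sd = 8,
                            background = 0.05, jitter_sd = 20,
                            seed = 1L) {
  if (!(p_lagging > 0 && p_lagging < 1)) {
    stop("p_lagging must lie strictly in (0, 1)")
  }
  if (depth < 1) stop("depth must be >= 1")
  if (!(background >= 0 && background < 1)) {
    stop("background fraction must lie in [0, 1)")
  }
  structure(list(name = name, p_lagging = p_lagging,
                 depth = as.integer(depth), frag_mean = frag_mean,
                 frag_sd = frag_sd, background = background,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "genotype_params")
}

#' Illustrative genotype presets
#'
#' Qualitative presets for the simulator: wild type with a slight lagging
#' bias, a Pol-epsilon-pathway mutant (strong lagging bias of parental
#' marks), an Mcm2-axis mutant (leading bias), and the double mutant in
#' which the biases neutralize. The numbers are simulator settings, not
#' measurements.
#'
#' @param depth Signal fragments per origin side for every preset.
#' @param seed Base seed; each preset gets an offset stream.
#' @return Named list of [genotype_params()] objects.
#' @export
genotype_presets <- function(depth = 400, seed = 1L) {
  p <- c(WT = 0.55, dpb3 = 0.80, mcm2_3A = 0.20, dpb3_mcm2_3A = 0.55)
  out <- lapply(seq_along(p), function(i) {
    genotype_params(names(p)[i], p[[i]], depth, seed = seed + i - 1L)
  })
  names(out) <- names(p)
  out
}

#' Simulate strand-resolved eSPAN fragments
#'
#' Emits mononucleosome-sized fragments at the origin-flanking
#' nucleosomes of a [make_genome()] fixture. For `mark = "parental"`, the
#' probability of the Watson strand is `p_lagging` at left-side
#' nucleosomes and `1 - p_lagging` at right-side nucleosomes; for
#' `mark = "new"` the probabilities are complemented (new histones take
#' the strand the parental ones avoid). Exactly
#' `depth * 2 * n_origins` signal fragments are emitted, plus
#' `round(background / (1 - background) * n_signal)` uniform background
#' fragments with fair strand choice.
#'
#' @param fixture A [make_genome()] result with at least one origin.
#' @param geno A [genotype_params()] object.
#' @param mark `"parental"` or `"new"`.
#' @return An [fragments()] table; the `mark` column carries `mark`.
#' @export
simulate_espan <- function(fixture, geno, mark = c("parental", "new")) {
  stopifnot(inherits(fixture, "genome_fixture"),
            inherits(geno, "genotype_params"))
  mark <- match.arg(mark)
  n_ori <- nrow(fixture$origins)
  if (n_ori < 1) stop("fixture has no origins")
  chrom_len <- unname(fixture$chrom_lengths["chrI"])

  nuc <- fixture$origin_nucs
  # dyad lookup: rows = origins, cols = the 20 positions -10..-1,+1..+10
  idx_levels <- c(-10:-1, 1:10)
  dyad_mat <- matrix(NA_real_, n_ori, length(idx_levels))
  dyad_mat[cbind(nuc$origin_id, match(nuc$index, idx_levels))] <- nuc$dyad

  n_sig <- geno$depth * 2L * n_ori
  n_bg <- round(geno$background / (1 - geno$background) * n_sig)

  withr::with_seed(geno$seed, {
    ori <- rep(seq_len(n_ori), each = 2L * geno$depth)
    side <- rep(rep(c(-1L, 1L), each = geno$depth), n_ori)
    k <- sample.int(10L, n_sig, replace = TRUE)
    col <- match(side * k, idx_levels)
    dyad <- dyad_mat[cbind(ori, col)]

    mid <- round(dyad + stats::rnorm(n_sig, 0, geno$jitter_sd))
    len <- pmin(170, pmax(120, round(
      stats::rnorm(n_sig, geno$frag_mean, geno$frag_sd))))
    start <- pmax(0, mid - len %/% 2L)
    start <- pmin(start, chrom_len - len)
    p_w_lagging <- if (mark == "parental") geno$p_lagging else
      1 - geno$p_lagging
    # lagging nascent strand is Watson left of the origin, Crick right
    p_watson <- ifelse(side < 0, p_w_lagging, 1 - p_w_lagging)
    strand <- ifelse(stats::runif(n_sig) < p_watson, "+", "-")

    if (n_bg > 0) {
      blen <- pmin(170, pmax(120, round(
        stats::rnorm(n_bg, geno$frag_mean, geno$frag_sd))))
      bstart <- floor(stats::runif(n_bg, 0, chrom_len - blen))
      start <- c(start, bstart)
      len <- c(len, blen)
      strand <- c(strand, ifelse(stats::runif(n_bg) < 0.5, "+", "-"))
    }
    as_fragments(data.frame(
      chrom = "chrI", start = start, end = start + len,
      strand = strand, mark = mark, stringsAsFactors = FALSE))
  })
}

#' Simulate MNase-seq fragments over positioned nucleosomes
#'
#' Fragment midpoints are drawn Normal(dyad, `positioning_sd`) at dyads
#' sampled uniformly from the fixture's origin-flanking and genic
#' nucleosomes; a `background` fraction of the `depth` total is placed
#' uniformly instead (`background = 1` gives a fully unpositioned,
#' naked-DNA-like library). Lengths are clipped to 149-170 bp and the
#' library is strandless (fair +/- assignment).
#'
#' @param fixture A [make_genome()] result.
#' @param positioning_sd Midpoint standard deviation around the dyad
#'   (bp, >= 0); 0 places every midpoint exactly at a dyad.
#' @param depth Total number of fragments emitted (exactly).
#' @param background Fraction in \[0, 1\] of fragments placed uniformly.
#' @param seed Integer seed.
#' @return An [fragments()] table with `mark = "mnase"`.
#' @export
simulate_mnase <- function(fixture, positioning_sd = 20, depth = 1e5,
                           background = 0, seed = 1L) {
  stopifnot(inherits(fixture, "genome_fixture"))
  if (positioning_sd < 0) stop("positioning_sd must be >= 0")
  if (depth < 1) stop("depth must be >= 1")
  if (!(background >= 0 && background <= 1)) {
    stop("background fraction must lie in [0, 1]")
  }
  depth <- as.integer(depth)
  dyads <- rbind(
    data.frame(chrom = fixture$origin_nucs$chrom,
               dyad = fixture$origin_nucs$dyad),
    if (!is.null(fixture$gene_nucs))
      data.frame(chrom = fixture$gene_nucs$chrom,
                 dyad = fixture$gene_nucs$dyad)
  )
  n_bg <- round(background * depth)
  n_sig <- depth - n_bg

  withr::with_seed(as.integer(seed), {
    len <- pmin(170, pmax(149, round(stats::rnorm(depth, 157, 8))))
    if (n_sig > 0) {
      pick <- sample.int(nrow(dyads), n_sig, replace = TRUE)
      chrom <- dyads$chrom[pick]
      mid <- round(dyads$dyad[pick] +
                     stats::rnorm(n_sig, 0, positioning_sd))
    } else {
      chrom <- character(0); mid <- numeric(0)
    }
    if (n_bg > 0) {
      bchrom <- sample(names(fixture$chrom_lengths), n_bg, replace = TRUE)
      bmid <- floor(stats::runif(
        n_bg, 90, fixture$chrom_lengths[bchrom] - 90))
      chrom <- c(chrom, bchrom)
      mid <- c(mid, bmid)
    }
    clen <- unname(fixture$chrom_lengths[chrom])
    start <- pmax(0, mid - len %/% 2L)
    start <- pmin(start, clen - len)
    strand <- ifelse(stats::runif(depth) < 0.5, "+", "-")
    as_fragments(data.frame(
      chrom = chrom, start = start, end = start + len,
      strand = strand, mark = "mnase", stringsAsFactors = FALSE))
  })
}

#' Ground-truth phenotype parameters for the simulator
#'
#' @param genotype Character vector of genotype labels.
#' @param silencing_rate Per-division apparent silencing-loss probability
#'   in \[0, 1\] (per genotype).
#' @param hr_freq Homologous-recombination frequency per viable cell in
#'   \[0, 1\].
#' @param foci_prob Probability a cell shows at least one Rad52 focus.
#' @return A data.frame of class `phenotype_truth`.
#' @export
phenotype_truth <- function(genotype, silencing_rate, hr_freq, foci_prob) {
  vals <- c(silencing_rate, hr_freq, foci_prob)
  if (any(vals < 0 | vals > 1)) {
    stop("all phenotype probabilities must lie in [0, 1]")
  }
  structure(data.frame(genotype = as.character(genotype),
                       silencing_rate = silencing_rate,
                       hr_freq = hr_freq, foci_prob = foci_prob,
                       stringsAsFactors = FALSE),
            class = c("phenotype_truth", "data.frame"))
}

#' Simulate phenotype assay tables
#'
#' Generates, per genotype: a flow-cytometry event table for the
#' silencing-loss (CRASH-style) assay, colony counts for the HR
#' frequency assay, and Rad52-focus counts per imaging field.
#' CRASH events are multinomial over RFP+GFP+ / RFP+GFP- / other; the
#' selective-plate colony count is Binomial(cells plated, HR frequency)
#' per replicate colony with the viable-plate count Poisson around
#' cells plated / dilution; focus-positive cells are
#' Binomial(cells per field, focus probability).
#'
#' @param truth A [phenotype_truth()] table.
#' @param n_events Flow events analysed per colony (default 50000).
#' @param n_colonies Colonies per genotype for the CRASH assay.
#' @param n_replicates Independent colonies per genotype for the HR assay.
#' @param n_cells Cells plated on the selective plate per HR replicate.
#' @param dilution Dilution factor applied before the viable-count plate.
#' @param n_fields Imaging fields per genotype.
#' @param cells_per_field Cells scored per imaging field.
#' @param p_other Fraction of flow events outside the RFP+ gate.
#' @param seed Integer seed.
#' @return A list of class `phenotype_tables` with data.frames `crash`
#'   (genotype, colony, rfp_gfp_pos, rfp_gfp_neg, other), `hr`
#'   (genotype, replicate, selective, viable, dilution) and `foci`
#'   (genotype, field, counted, positive).
#' @export
simulate_phenotypes <- function(truth, n_events = 50000L,
                                n_colonies = 10L, n_replicates = 6L,
                                n_cells = 1e6, dilution = 1e4,
                                n_fields = 3L, cells_per_field = 500L,
                                p_other = 0.1, seed = 1L) {
  stopifnot(inherits(truth, "phenotype_truth"))
  if (!(p_other >= 0 && p_other < 1)) stop("p_other must lie in [0, 1)")
  withr::with_seed(as.integer(seed), {
    crash <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      other <- stats::rbinom(n_colonies, n_events, p_other)
      potential <- n_events - other
      pos <- stats::rbinom(n_colonies, potential,
                           truth$silencing_rate[i])
      data.frame(genotype = truth$genotype[i],
                 colony = seq_len(n_colonies),
                 rfp_gfp_pos = pos, rfp_gfp_neg = potential - pos,
                 other = other, stringsAsFactors = FALSE)
    }))
    hr <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      data.frame(genotype = truth$genotype[i],
                 replicate = seq_len(n_replicates),
                 selective = stats::rbinom(n_replicates, n_cells,
                                           truth$hr_freq[i]),
                 viable = stats::rpois(n_replicates, n_cells / dilution),
                 dilution = dilution, stringsAsFactors = FALSE)
    }))
    foci <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      data.frame(genotype = truth$genotype[i],
                 field = seq_len(n_fields),
                 counted = cells_per_field,
                 positive = stats::rbinom(n_fields, cells_per_field,
                                          truth$foci_prob[i]),
                 stringsAsFactors = FALSE)
    }))
    structure(list(crash = crash, hr = hr, foci = foci),
              class = "phenotype_tables")
  })
}
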