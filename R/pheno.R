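sem_of <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Apparent silencing-loss rate from flow-cytometry event tables
#'
#' The per-colony rate is the number of RFP+GFP+ events (cells that have
#' recently lost silencing and undergone the reporter switch) divided by
#' the total number of cells with the potential to lose silencing
#' (RFP+GFP+ plus RFP+GFP-). Events outside the RFP+ gate ("other") are
#' excluded from the denominator. A colony with an empty denominator is
#' flagged missing rather than reported as zero.
#'
#' @param events data.frame with columns `genotype`, `colony`,
#'   `rfp_gfp_pos`, `rfp_gfp_neg` (and optionally `other`), e.g. the
#'   `crash` table from [simulate_phenotypes()].
#' @return List with `per_colony` (input plus `rate`) and `summary`
#'   (per genotype: `mean`, `sem`, `n`).
#' @export
silencing_loss_rate <- function(events) {
  need <- c("genotype", "rfp_gfp_pos", "rfp_gfp_neg")
  stopifnot(all(need %in% names(events)))
  if (any(events$rfp_gfp_pos < 0 | events$rfp_gfp_neg < 0)) {
    stop("event counts must be non-negative")
  }
  denom <- events$rfp_gfp_pos + events$rfp_gfp_neg
  events$rate <- ifelse(denom > 0, events$rfp_gfp_pos / denom, NA_real_)
  genos <- unique(events$genotype)
  summ <- data.frame(
    genotype = genos,
    mean = vapply(genos, function(g)
      mean(events$rate[events$genotype == g], na.rm = TRUE), numeric(1)),
    sem = vapply(genos, function(g)
      sem_of(events$rate[events$genotype == g]), numeric(1)),
    n = vapply(genos, function(g)
      sum(!is.na(events$rate[events$genotype == g])), integer(1)),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  list(per_colony = events, summary = summ)
}

#' Median homologous-recombination frequency per viable cell
#'
#' Each replicate colony contributes a frequency: the selective-plate
#' colony count divided by the viable cell number (viable-plate count
#' times its dilution factor). The strain statistic is the median over
#' replicates; with an even number of replicates, the mean of the two
#' central values.
#'
#' @param counts data.frame with columns `genotype`, `replicate`,
#'   `selective`, `viable` and optionally `dilution` (default 1), e.g.
#'   the `hr` table from [simulate_phenotypes()].
#' @return List with `per_replicate` (input plus `frequency`) and
#'   `summary` (per genotype: `median`, `n`).
#' @export
hr_frequency <- function(counts) {
  need <- c("genotype", "selective", "viable")
  stopifnot(all(need %in% names(counts)))
  if (!"dilution" %in% names(counts)) counts$dilution <- 1
  bad <- which(counts$viable <= 0)
  if (length(bad) > 0) {
    stop("viable count must be positive (replicate row ",
         paste(bad, collapse = ", "), ")")
  }
  counts$frequency <- counts$selective /
    (counts$viable * counts$dilution)
  genos <- unique(counts$genotype)
  summ <- data.frame(
    genotype = genos,
    median = vapply(genos, function(g)
      stats::median(counts$frequency[counts$genotype == g]), numeric(1)),
    n = vapply(genos, function(g)
      sum(counts$genotype == g), integer(1)),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  list(per_replicate = counts, summary = summ)
}

#' Relative HR frequency of a mutant versus a reference strain
#'
#' Ratio of the mutant's median frequency to the reference strain's
#' median frequency (a ratio of medians, not a mean of per-replicate
#' ratios).
#'
#' @param hr A [hr_frequency()] result.
#' @param mutant,reference Genotype labels present in the summary.
#' @return A single number; 1.0 means equal medians.
#' @export
relative_hr <- function(hr, mutant, reference = "WT") {
  s <- hr$summary
  for (g in c(mutant, reference)) {
    if (!g %in% s$genotype) stop("genotype not present: ", g)
  }
  s$median[s$genotype == mutant] / s$median[s$genotype == reference]
}

#' Percentage of cells with Rad52 foci
#'
#' Per imaging field, `100 * positive / counted`; per strain, the mean
#' over fields with its standard error.
#'
#' @param table data.frame with columns `genotype`, `counted`,
#'   `positive`, e.g. the `foci` table from [simulate_phenotypes()].
#' @return List with `per_field` (input plus `percent`) and `summary`
#'   (per genotype: `mean`, `sem`, `n`).
#' @export
foci_fraction <- function(table) {
  need <- c("genotype", "counted", "positive")
  stopifnot(all(need %in% names(table)))
  if (any(table$counted <= 0)) stop("counted must be positive")
  if (any(table$positive > table$counted)) {
    stop("positive cells cannot exceed counted cells")
  }
  table$percent <- 100 * table$positive / table$counted
  genos <- unique(table$genotype)
  summ <- data.frame(
    genotype = genos,
    mean = vapply(genos, function(g)
      mean(table$percent[table$genotype == g]), numeric(1)),
    sem = vapply(genos, function(g)
      sem_of(table$percent[table$genotype == g]), numeric(1)),
    n = vapply(genos, function(g)
      sum(table$genotype == g), integer(1)),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  list(per_field = table, summary = summ)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test with
#' k - 1 and N - k degrees of freedom), as used to compare a mutant's
#' replicate measurements against wild type. With two groups the F
#' statistic equals the square of the equal-variance two-sample t
#' statistic. Degenerate input (all observations identical) has an
#' undefined F and is flagged rather than returned as a number.
#'
#' @param groups Named list of >= 2 numeric vectors, each with >= 2
#'   observations.
#' @return List: `f` statistic, `p` upper-tail p-value, `df` (numerator,
#'   denominator), `defined` (FALSE when total variance is zero).
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 observations")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups),
                  vapply(groups, length, integer(1))))
  k <- length(groups); n <- length(values)
  if (stats::var(values) == 0) {
    return(list(f = NA_real_, p = NA_real_, df = c(k - 1L, n - k),
                defined = FALSE))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(f = unname(fit$statistic), p = unname(fit$p.value),
       df = unname(fit$parameter), defined = TRUE)
}

#' Soluble-histone level normalized to PGK1, relative to a reference
#' strain
#'
#' Per replicate blot, the soluble-histone signal is divided by the
#' soluble-PGK1 signal of the same lane (loading/fraction control); the
#' normalized values are then scaled so the reference strain's mean is
#' 1.0. Scaling every signal by a common factor (exposure) leaves the
#' result unchanged.
#'
#' @param table data.frame with columns `strain`, `replicate`,
#'   `histone`, `pgk1` (positive signals).
#' @param reference Reference strain name (present in the table).
#' @return List with `per_replicate` (input plus `normalized`,
#'   `relative`) and `summary` (per strain: `mean`, `sem`, `n`).
#' @export
soluble_histone_ratio <- function(table, reference = "WT") {
  need <- c("strain", "histone", "pgk1")
  stopifnot(all(need %in% names(table)))
  if (any(table$histone <= 0 | table$pgk1 <= 0)) {
    stop("blot signals must be positive")
  }
  if (!reference %in% table$strain) {
    stop("reference strain not in table: ", reference)
  }
  table$normalized <- table$histone / table$pgk1
  ref_mean <- mean(table$normalized[table$strain == reference])
  table$relative <- table$normalized / ref_mean
  strains <- unique(table$strain)
  summ <- data.frame(
    strain = strains,
    mean = vapply(strains, function(s)
      mean(table$relative[table$strain == s]), numeric(1)),
    sem = vapply(strains, function(s)
      sem_of(table$relative[table$strain == s]), numeric(1)),
    n = vapply(strains, function(s)
      sum(table$strain == s), integer(1)),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  list(per_replicate = table, summary = summ)
}
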