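# Independent reference implementations and fixture builders used across
# the suite. These stay deliberately naive (per-fragment loops, direct
# formulas) so they are a different route from the package code.

# brute-force per-fragment counting: scan every nucleosome interval
naive_count_by_nucleosome <- function(frags, nucmap) {
  pos <- c(-10:-1, 1:10)
  ostart <- tapply(nucmap$start, nucmap$origin_id, min)
  ochrom <- tapply(nucmap$chrom, nucmap$origin_id, `[`, 1L)
  oid <- names(ostart)[order(unlist(ochrom), unlist(ostart))]
  counts <- array(0L, dim = c(length(oid), length(pos), 2L),
                  dimnames = list(origin = oid,
                                  position = as.character(pos),
                                  strand = c("W", "C")))
  for (i in seq_len(nrow(frags))) {
    mid <- floor((frags$start[i] + frags$end[i]) / 2)
    for (j in seq_len(nrow(nucmap))) {
      if (frags$chrom[i] == nucmap$chrom[j] &&
          mid >= nucmap$start[j] && mid < nucmap$end[j]) {
        o <- as.character(nucmap$origin_id[j])
        p <- as.character(nucmap$index[j])
        s <- if (frags$strand[i] == "+") "W" else "C"
        counts[o, p, s] <- counts[o, p, s] + 1L
      }
    }
  }
  counts
}

naive_bias <- function(counts, pc) {
  m <- matrix(NA_real_, dim(counts)[1], dim(counts)[2],
              dimnames = list(dimnames(counts)[[1]],
                              dimnames(counts)[[2]]))
  for (o in seq_len(dim(counts)[1])) {
    for (p in seq_len(dim(counts)[2])) {
      w <- counts[o, p, "W"] + pc
      cc <- counts[o, p, "C"] + pc
      if (w > 0 && cc > 0) m[o, p] <- log2(w / cc)
    }
  }
  m
}

# random stranded fragments scattered over a fixture's origin windows
random_espan_fragments <- function(fixture, n, seed) {
  withr::with_seed(seed, {
    nuc <- fixture$origin_nucs
    pick <- sample.int(nrow(nuc), n, replace = TRUE)
    mid <- nuc$dyad[pick] + sample(-120:120, n, replace = TRUE)
    len <- sample(120:170, n, replace = TRUE)
    start <- pmax(0, mid - len %/% 2)
    fragments(nuc$chrom[pick], start, start + len,
              sample(c("+", "-"), n, replace = TRUE))
  })
}

# 99% interval for a binomial proportion estimate at truth p
binom_interval <- function(p, n, conf = 0.99) {
  a <- (1 - conf) / 2
  stats::qbinom(c(a, 1 - a), n, p) / n
}

# exact 99% interval for the median of n_rep iid Poisson(lambda) counts
# (even n_rep: mean of the two central order statistics), by enumeration
# of the order-statistic CDF on an integer grid
pois_median_interval <- function(lambda, n_rep = 6, conf = 0.99) {
  a <- (1 - conf) / 2
  grid <- 0:stats::qpois(1 - 1e-12, lambda)
  F <- stats::ppois(grid, lambda)
  k_lo <- n_rep / 2        # X_(k_lo) <= median <= X_(k_lo + 1)
  # P(X_(k) <= m) = P(at least k of n draws <= m)
  cdf_lo <- 1 - stats::pbinom(k_lo - 1, n_rep, F)      # CDF of X_(k_lo)
  surv_hi <- stats::pbinom(k_lo, n_rep, F)             # P(X_(k_lo+1) > m)
  lo <- grid[min(which(cdf_lo > a))]     # P(median < lo) <= a
  hi <- grid[min(which(surv_hi <= a))]   # P(median > hi) <= a
  c(lo, hi)
}

small_fixture <- function(n_origins = 3, n_genes = 4,
                          chrom_length = 1.2e5, seed = 1) {
  make_genome(n_origins, n_genes, chrom_length, seed = seed)
}

espan_profile <- function(fixture, geno, mark = "parental",
                          pseudocount = 1) {
  frags <- filter_fragments(simulate_espan(fixture, geno, mark))
  counts <- count_by_nucleosome(frags, fixture$origin_nucs)
  average_bias_profile(bias_matrix(counts, pseudocount))
}
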