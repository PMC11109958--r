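test_that("genome layout honours nucleosome geometry invariants", {
  gf <- make_genome(n_origins = 5, n_genes = 4, chrom_length = 2e5,
                    spacing = 165, nfr_width = 140, seed = 7)
  nuc <- gf$origin_nucs
  # 20 flanking dyads per origin, 10 per side, no position 0
  expect_equal(nrow(nuc), 5 * 20)
  expect_true(all(table(nuc$origin_id) == 20))
  expect_false(any(nuc$index == 0))
  for (o in unique(nuc$origin_id)) {
    d <- nuc[nuc$origin_id == o, ]
    mid <- gf$origins$midpoint[gf$origins$origin_id == o]
    expect_true(all(d$dyad[d$index < 0] < mid))
    expect_true(all(d$dyad[d$index > 0] > mid))
    # adjacent dyads >= 147 bp apart, none inside the NFR
    expect_true(all(diff(sort(d$dyad)) >= 147))
    expect_false(any(abs(d$dyad - mid) < gf$nfr_width / 2))
    expect_false(is.unsorted(d$start[order(d$index)]))
  }
  expect_true(all(nuc$start >= 0 & nuc$end <= gf$chrom_lengths["chrI"]))
  # gene dyads all downstream of their TSS on the gene's strand
  g <- merge(gf$gene_nucs, gf$tss, by = c("gene_id", "chrom"))
  expect_true(all(ifelse(g$strand == "+", g$dyad > g$pos, g$dyad < g$pos)))
})

test_that("genome generation is deterministic and rejects impossible layouts", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_genome_fixture(make_genome(6, 3, 1.5e5, seed = 3), d1)
  write_genome_fixture(make_genome(6, 3, 1.5e5, seed = 3), d2)
  for (f in c("origins.bed", "tss.bed", "nucmap.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # window footprint is 21 x 165 = 3465 bp; 30 origins cannot fit in
  # 100 kb once windows must not overlap each other or the ends
  expect_error(make_genome(30, 0, 1e5), "cannot hold|overlap")
  expect_error(make_genome(3, 0, 5000), "cannot hold|overlap")
})

test_that("eSPAN simulator reproduces its per-side Watson probabilities", {
  gf <- small_fixture()
  n_check <- function(p, mark, seed) {
    geno <- genotype_params("x", p, depth = 4000, background = 0,
                            seed = seed)
    fr <- simulate_espan(gf, geno, mark)
    mid <- floor((fr$start + fr$end) / 2)
    ori_mid <- gf$origins$midpoint[
      findInterval(mid, gf$origins$midpoint - 2000)]
    left <- mid < ori_mid
    c(mean(fr$strand[left] == "+"), mean(fr$strand[!left] == "+"))
  }
  # symmetric null: both sides 0.5 within 3 binomial SDs (n = 12000/side)
  w <- n_check(0.5, "parental", 21)
  tol <- 3 * sqrt(0.25 / 12000)
  expect_true(all(abs(w - 0.5) < tol))
  # p = 0.75 parental: Watson fraction 0.75 left, 0.25 right (99% CI)
  w <- n_check(0.75, "parental", 22)
  ci <- binom_interval(0.75, 12000)
  expect_gt(w[1], ci[1]); expect_lt(w[1], ci[2])
  expect_gt(1 - w[2], ci[1]); expect_lt(1 - w[2], ci[2])
  # new-mark probabilities are the complement of parental
  w_new <- n_check(0.75, "new", 23)
  expect_lt(w_new[1], binom_interval(0.25, 12000)[2])
  expect_gt(w_new[2], binom_interval(0.75, 12000)[1])
})

test_that("eSPAN simulator enforces contracts and conserves counts", {
  gf <- small_fixture()
  expect_error(genotype_params("x", 1.0, 10), "strictly in")
  expect_error(genotype_params("x", 0, 10), "strictly in")
  expect_error(genotype_params("x", 0.5, 0), "depth")
  expect_error(genotype_params("x", 0.5, 10, background = 1), "background")

  geno <- genotype_params("x", 0.6, depth = 50, background = 0.2,
                          seed = 5)
  fr <- simulate_espan(gf, geno, "parental")
  n_sig <- 50 * 2 * nrow(gf$origins)
  expect_equal(nrow(fr), n_sig + round(0.2 / 0.8 * n_sig))
  expect_true(all(fr$start >= 0 & fr$start < fr$end &
                    fr$end <= gf$chrom_lengths["chrI"]))
  expect_true(all(fr$end - fr$start >= 120 & fr$end - fr$start <= 170))
  # determinism: same params, byte-identical output
  expect_identical(fr, simulate_espan(gf, geno, "parental"))
})

test_that("MNase simulator places midpoints as configured", {
  gf <- small_fixture()
  # degenerate positioning: every midpoint exactly at a dyad
  fr0 <- simulate_mnase(gf, positioning_sd = 0, depth = 2000,
                        background = 0, seed = 9)
  mid <- floor((fr0$start + fr0$end) / 2)
  dyads <- sort(unique(c(gf$origin_nucs$dyad, gf$gene_nucs$dyad)))
  expect_true(all(mid %in% dyads))
  expect_true(all(fr0$end - fr0$start >= 149 &
                    fr0$end - fr0$start <= 170))
  expect_equal(nrow(fr0), 2000)
  # empirical midpoint spread around one dyad recovers positioning_sd
  fr <- simulate_mnase(gf, positioning_sd = 20, depth = 2e5,
                       background = 0, seed = 10)
  mid <- floor((fr$start + fr$end) / 2)
  d1 <- gf$origin_nucs$dyad[1]
  near <- mid[abs(mid - d1) < 80 &
                fr$chrom == gf$origin_nucs$chrom[1]]
  expect_gt(length(near), 1000)
  expect_lt(abs(sd(near - d1) - 20) / 20, 0.05)
  expect_error(simulate_mnase(gf, -1, 100), "positioning_sd")
  expect_error(simulate_mnase(gf, 20, 0), "depth")
  expect_error(simulate_mnase(gf, 20, 100, background = 1.5),
               "background")
})

test_that("phenotype simulator recovers its ground truth", {
  truth <- phenotype_truth("WT", silencing_rate = 0.004,
                           hr_freq = 1e-4, foci_prob = 0.02)
  expect_error(phenotype_truth("x", 1.2, 0, 0), "\\[0, 1\\]")
  pt <- simulate_phenotypes(truth, n_events = 50000, n_colonies = 10,
                            n_replicates = 6, n_cells = 1e6, seed = 31)
  # zero-rate genotype emits zero positive events
  pt0 <- simulate_phenotypes(phenotype_truth("z", 0, 0, 0), seed = 1)
  expect_true(all(pt0$crash$rfp_gfp_pos == 0))
  # recovered CRASH rate inside the 99% binomial interval at truth
  est <- sum(pt$crash$rfp_gfp_pos) /
    sum(pt$crash$rfp_gfp_pos + pt$crash$rfp_gfp_neg)
  ci <- binom_interval(0.004, sum(pt$crash$rfp_gfp_pos +
                                    pt$crash$rfp_gfp_neg))
  expect_gt(est, ci[1]); expect_lt(est, ci[2])
  # median selective count near 100 within the exact Poisson spread
  med <- median(pt$hr$selective)
  iv <- pois_median_interval(100, 6)
  expect_gte(med, iv[1]); expect_lte(med, iv[2])
  expect_true(all(pt$foci$positive <= pt$foci$counted))
})
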