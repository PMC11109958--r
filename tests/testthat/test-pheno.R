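test_that("silencing-loss rate divides switched by switch-capable cells", {
  ev <- data.frame(genotype = c("WT", "WT", "WT"), colony = 1:3,
                   rfp_gfp_pos = c(5, 0, 10),
                   rfp_gfp_neg = c(95, 50000, 0),
                   other = c(10, 3, 0))
  out <- silencing_loss_rate(ev)
  expect_equal(out$per_colony$rate, c(0.05, 0, 1))
  # "other" events never enter the denominator
  ev2 <- transform(ev, other = other + 1000)
  expect_equal(silencing_loss_rate(ev2)$per_colony$rate,
               out$per_colony$rate)
  # zero denominator flagged missing, not zero
  ev$rfp_gfp_pos[1] <- 0; ev$rfp_gfp_neg[1] <- 0
  expect_true(is.na(silencing_loss_rate(ev)$per_colony$rate[1]))
  expect_error(silencing_loss_rate(transform(ev, rfp_gfp_pos = -1)),
               "non-negative")
})

test_that("HR frequency is the median per viable cell, dilution-corrected", {
  ct <- data.frame(genotype = "WT", replicate = 1:3,
                   selective = c(1, 2, 3), viable = 100, dilution = 100)
  out <- hr_frequency(ct)
  expect_equal(out$per_replicate$frequency, c(1, 2, 3) * 1e-4)
  expect_equal(out$summary$median, 2e-4)
  # even number of replicates: mean of the central pair
  ct4 <- data.frame(genotype = "WT", replicate = 1:4,
                    selective = c(1, 2, 4, 10), viable = 1,
                    dilution = 1)
  expect_equal(hr_frequency(ct4)$summary$median, 3)
  expect_error(hr_frequency(transform(ct, viable = 0)), "replicate")
  # median robustness: one wild replicate moves it at most to a
  # neighbouring observed value
  ct6 <- data.frame(genotype = "WT", replicate = 1:6,
                    selective = c(90, 95, 100, 105, 110, 115),
                    viable = 1, dilution = 1)
  base <- hr_frequency(ct6)$summary$median
  ct6$selective[6] <- 1e9
  moved <- hr_frequency(ct6)$summary$median
  expect_lte(abs(moved - base), 5)
})

test_that("relative HR divides mutant median by reference median", {
  ct <- rbind(
    data.frame(genotype = "WT", replicate = 1:3,
               selective = c(10, 20, 30), viable = 1, dilution = 1),
    data.frame(genotype = "mut", replicate = 1:3,
               selective = c(5, 10, 15), viable = 1, dilution = 1))
  hr <- hr_frequency(ct)
  expect_equal(relative_hr(hr, "mut", "WT"), 0.5)
  expect_equal(relative_hr(hr, "WT", "WT"), 1.0)
  expect_error(relative_hr(hr, "nope", "WT"), "not present")
})

test_that("focus fractions give percentages with two-point mean/SEM", {
  tab <- data.frame(genotype = "WT", field = 1:2, counted = 500,
                    positive = c(10, 20))
  out <- foci_fraction(tab)
  expect_equal(out$per_field$percent, c(2, 4))
  expect_equal(out$summary$mean, 3)
  expect_equal(out$summary$sem, 1)
  expect_equal(foci_fraction(data.frame(
    genotype = "z", field = 1, counted = 500, positive = 0
  ))$summary$mean, 0)
  expect_error(foci_fraction(transform(tab, positive = 501)), "exceed")
})

test_that("one-way ANOVA matches textbook sums of squares and the t test", {
  # identical groups: F = 0, p = 1
  out <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(out$f, 0)
  expect_equal(out$p, 1)
  # hand-computed 3-group table: groups {1,2,3},{2,3,4},{6,7,8}
  # grand mean 4; SSB = 3*(2-4)^2+3*(3-4)^2+3*(7-4)^2 = 42; SSW = 6
  # F = (42/2)/(6/6) = 21, df (2, 6)
  out <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(6, 7, 8)))
  expect_equal(out$f, 21, tolerance = 1e-12)
  expect_equal(unname(out$df), c(2, 6))
  expect_equal(out$p, stats::pf(21, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # two-group F equals the squared equal-variance t statistic
  withr::with_seed(99, {
    for (i in 1:25) {
      x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = 0.5)
      f <- one_way_anova(list(x, y))$f
      t <- stats::t.test(x, y, var.equal = TRUE)$statistic
      expect_equal(f, unname(t)^2, tolerance = 1e-9)
    }
  })
  # invariances: shift leaves F unchanged; scale leaves F unchanged
  g <- list(c(1, 2, 3, 4), c(2, 4, 5, 7))
  f0 <- one_way_anova(g)$f
  expect_equal(one_way_anova(lapply(g, `+`, 100))$f, f0)
  expect_equal(one_way_anova(lapply(g, `*`, 3.7))$f, f0)
  # degenerate input flagged, not numeric
  out <- one_way_anova(list(c(5, 5), c(5, 5)))
  expect_false(out$defined)
  expect_true(is.na(out$f))
  expect_error(one_way_anova(list(1, c(2, 3))), "at least 2")
})

test_that("soluble-histone ratios normalize to PGK1 then the reference", {
  tab <- expand.grid(strain = c("WT", "dpb3", "rad53"), replicate = 1:3,
                     stringsAsFactors = FALSE)
  tab$histone <- c(1, 2, 4, 1.2, 2.2, 4.4, 0.8, 1.8, 3.6)
  tab$pgk1 <- rep(c(1, 1, 2), 3)
  out <- soluble_histone_ratio(tab, reference = "WT")
  # WT normalized: 1, 1.2, 0.8 -> mean 1; relative summary by hand
  expect_equal(out$summary$mean[out$summary$strain == "WT"], 1)
  expect_equal(out$summary$mean[out$summary$strain == "dpb3"],
               mean(c(2, 2.2, 1.8)))
  expect_equal(out$summary$mean[out$summary$strain == "rad53"],
               mean(c(2, 2.2, 1.8)))
  # common exposure factor cancels
  out2 <- soluble_histone_ratio(
    transform(tab, histone = histone * 7, pgk1 = pgk1 * 7), "WT")
  expect_equal(out2$summary$mean, out$summary$mean)
  expect_error(soluble_histone_ratio(transform(tab, pgk1 = 0)),
               "positive")
  expect_error(soluble_histone_ratio(tab, "nope"), "reference")
})
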