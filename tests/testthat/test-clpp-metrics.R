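test_that("awcd averages replicate-averaged substrate ODs", {
  # 4-substrate polymer subset, single replicate: hand mean
  ps <- makeSeries(substrate = paste0("sub", 1:4), replicate = rep(1L, 4),
                   times = 24, od = c(0.2, 0.4, 0.0, 0.6),
                   category = rep("polymers", 4))
  expect_equal(awcd(ps, 24), 0.3)
  expect_equal(awcd(ps, 24, substrates = c("sub1", "sub2")), 0.3)
  expect_error(awcd(ps, 48), "not on the series grid")
  expect_error(awcd(ps, 24, substrates = character(0)), "empty")

  # replicates averaged per substrate before the substrate mean
  ps2 <- makeSeries(substrate = c("a", "a", "b"), replicate = c(1L, 2L, 1L),
                    times = 24, od = c(0.2, 0.4, 0.9))
  expect_equal(awcd(ps2, 24), mean(c(0.3, 0.9)))

  # zero and constant cases
  ps0 <- makeSeries(paste0("s", 1:31), rep(1L, 31), times = 24,
                    od = rep(0, 31))
  expect_equal(awcd(ps0, 24), 0)
  psc <- makeSeries(paste0("s", 1:31), rep(1L, 31), times = 24,
                    od = rep(0.5, 31))
  expect_equal(awcd(psc, 24), 0.5)
})

test_that("awcdSeries traces the mean of noise-free logistic inputs", {
  lay <- ecoPlateLayout()
  subs <- substrates(lay)
  K <- seq(0.5, 2, length.out = 31)
  cfg <- plateSimConfig(K = K, r = 0.01, t0 = 480, turbidityMean = 0,
                        turbiditySd = 0, odNoiseSd = 0, controlDrift = 0,
                        seed = 1)
  aff <- setNames(rep(1, 31), subs)
  sim <- simulatePlate(cfg, sampleProfile = aff, layout = lay)
  ps <- correctPlateSeries(sim$readings, lay)
  curve <- awcdSeries(ps)
  # K was assigned to substrates in layout order; the analytic AWCD is the
  # mean of the 31 logistic curves
  Kmap <- setNames(sim$params$K, sim$params$substrate)
  analytic <- vapply(curve$time_h, function(t)
    mean(Kmap / (1 + exp(-0.01 * (t - 480)))), 0)
  expect_equal(curve$awcd, analytic, tolerance = 1e-9)

  ps1 <- makeSeries("a", 1L, times = 24, od = 0.2)
  expect_equal(nrow(awcdSeries(ps1)), 1L)
})

test_that("richness counts substrates above threshold at consecutive timepoints", {
  times <- (1:8) * 24
  odrow <- function(hits) { v <- rep(0.1, 8); v[hits] <- 0.8; v }
  od <- rbind(
    odrow(5:6), odrow(5:6), odrow(5:6), odrow(5:6), odrow(5:6),  # 5 pass
    odrow(3), odrow(7),                                          # isolated
    matrix(0.1, 24, 8))
  ps <- makeSeries(paste0("s", 1:31), rep(1L, 31), times, od)
  expect_equal(substrateRichness(ps), 5L)
  expect_equal(substrateRichness(ps, threshold = 0.05), 31L)
  expect_equal(substrateRichness(ps, threshold = 2), 0L)
  expect_error(substrateRichness(makeSeries("a", 1L, 24, 0.9)),
               "at least 2 timepoints")
  # the OD-sum variant adds the qualifying substrates' peak ODs
  expect_equal(substrateRichness(ps, statistic = "sum"), 5 * 0.8)
})

test_that("richness is monotone nonincreasing in the threshold", {
  set.seed(42)
  od <- matrix(runif(31 * 6, 0, 1.2), 31, 6)
  ps <- makeSeries(paste0("s", 1:31), rep(1L, 31), (1:6) * 24, od)
  r <- vapply(seq(0, 1.2, by = 0.1), function(th)
    substrateRichness(ps, threshold = th), 0L)
  expect_true(all(diff(r) <= 0))
})

test_that("substrate proportions normalize colour development", {
  ps <- makeSeries(c("a", "b", "c"), rep(1L, 3), times = 24,
                   od = c(0.2, 0.2, 0.4))
  expect_equal(unname(substratePi(ps, 24)), c(0.25, 0.25, 0.5))
  expect_equal(sum(substratePi(ps, 24)), 1)

  one <- makeSeries(c("a", "b"), rep(1L, 2), 24, c(0.8, 0))
  expect_equal(unname(substratePi(one, 24)), c(1, 0))
  eq <- makeSeries(paste0("s", 1:31), rep(1L, 31), 24, rep(0.3, 31))
  expect_equal(unname(substratePi(eq, 24)), rep(1 / 31, 31))

  zero <- makeSeries(c("a", "b"), rep(1L, 2), 24, c(0, 0))
  expect_error(substratePi(zero, 24), "undefined")
})

test_that("Simpson and Shannon follow the plate-profiling conventions", {
  expect_equal(simpsonIndex(1), 0)
  expect_equal(shannonIndex(1), 0)
  expect_equal(simpsonIndex(rep(1 / 31, 31)), log(31))
  expect_equal(shannonIndex(rep(1 / 31, 31)), log(31))
  expect_equal(simpsonIndex(c(0.5, 0.5)), -log(0.5))
  expect_equal(shannonIndex(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  expect_equal(giniSimpson(c(0.5, 0.5)), 0.5)
  expect_error(simpsonIndex(numeric(0)), "empty")
  expect_error(shannonIndex(c(0.7, 0.7)), "sum to 1")
})

test_that("diversity indices are maximal at uniform Pi and bounded by richness", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:31, 1)
    pi <- runif(n); pi <- pi / sum(pi)
    H <- shannonIndex(pi)
    D <- simpsonIndex(pi)
    expect_lte(H, log(sum(pi > 0)) + 1e-12)
    expect_lte(H, shannonIndex(rep(1 / n, n)) + 1e-12)
    expect_lte(D, simpsonIndex(rep(1 / n, n)) + 1e-12)
  }
  # equality iff uniform
  expect_equal(shannonIndex(rep(0.25, 4)), log(4))
})

test_that("category utilization is the per-category AWCD", {
  sub <- paste0("s", 1:6)
  cat6 <- c("amino_acids", "amino_acids", "polymers", "polymers",
            "amines", "amines")
  ps <- makeSeries(sub, rep(1L, 6), 24, od = c(0.6, 0.6, 0, 0, 0, 0),
                   category = cat6)
  cu <- categoryUtilization(ps, 24)
  expect_equal(cu[["amino_acids"]], 0.6)
  expect_equal(cu[["polymers"]], 0)
  expect_equal(cu[["amines"]], 0)

  # hand means per category
  ps2 <- makeSeries(sub, rep(1L, 6), 24, od = c(0.2, 0.4, 0.1, 0.5, 0.9, 0.3),
                    category = cat6)
  cu2 <- categoryUtilization(ps2, 24)
  expect_equal(cu2[["amino_acids"]], 0.3)
  expect_equal(cu2[["polymers"]], 0.3)
  expect_equal(cu2[["amines"]], 0.6)

  # overall AWCD equals the category-size-weighted mean
  sizes <- table(cat6)[names(cu2)]
  expect_equal(awcd(ps2, 24),
               sum(cu2 * as.vector(sizes)) / sum(sizes))
})

test_that("scaling corrected ODs scales AWCD and leaves Pi, D, H unchanged", {
  set.seed(3)
  od <- matrix(runif(62, 0.01, 1), 31, 2)
  ps1 <- makeSeries(paste0("s", 1:31), rep(1L, 31), c(24, 48), od)
  ps3 <- makeSeries(paste0("s", 1:31), rep(1L, 31), c(24, 48), 3 * od)
  expect_equal(awcd(ps3, 48), 3 * awcd(ps1, 48))
  expect_equal(substratePi(ps3, 48), substratePi(ps1, 48))
  expect_equal(simpsonIndex(substratePi(ps3, 48)),
               simpsonIndex(substratePi(ps1, 48)))
  expect_equal(shannonIndex(substratePi(ps3, 48)),
               shannonIndex(substratePi(ps1, 48)))
})

test_that("phase detection finds exponential and stable periods", {
  # flat zero curve: both undefined
  flat <- detectPhases(seq(0, 480, 24), rep(0, 21))
  expect_true(all(is.na(flat)))

  # noise-free logistic, midpoint 240 h, steep rate: stable start within one
  # sampling interval of the analytic 99%-saturation time t0 + ln(99)/r
  tt <- seq(0, 2400, 24)
  L <- 1 / (1 + exp(-0.05 * (tt - 240)))
  ph <- detectPhases(tt, L, window = 1L)
  t99 <- 240 + log(99) / 0.05
  expect_lte(abs(ph[["t_stable_start"]] - t99), 24)
  expect_false(is.na(ph[["t_exp_start"]]))
  expect_lt(ph[["t_exp_start"]], ph[["t_stable_start"]])

  # linear ramp 0 -> 1 over days 0-20 then flat: stable starts at day 20
  tt2 <- seq(0, 720, 24)
  ramp <- pmin(tt2 / 480, 1)
  ph2 <- detectPhases(tt2, ramp, window = 1L)
  expect_equal(ph2[["t_stable_start"]], 480)

  expect_error(detectPhases(c(0, 48, 24), c(0, 1, 2)), "strictly increasing")
})

test_that("clppProfile bundles indices at the stable-phase reference time", {
  lay <- ecoPlateLayout()
  sim <- simulatePlate(plateSimConfig(seed = 8))
  ps <- correctPlateSeries(sim$readings, lay)
  p <- clppProfile(ps)
  expect_s4_class(p, "ClppProfile")
  expect_equal(sum(p@pi), 1, tolerance = 1e-9)
  expect_true(p@richness >= 0 && p@richness <= 31)
  expect_lte(p@shannon, log(31) + 1e-12)
  expect_true(p@refTime %in% plateTimes(ps))
  expect_equal(sort(unique(p@awcdByCategory$category)),
               sort(unique(wells(lay)$category[wells(lay)$category != "control"])))
  # explicit reference time is honoured
  p2 <- clppProfile(ps, refTime = 2400)
  expect_equal(p2@refTime, 2400)
})
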