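test_that("marker arithmetic: concentration and influx", {
  ## a 15,319 grains/cm3 spike, 200 pollen against 100 markers
  expect_equal(concentration(200, 100, 15319), 30638)
  expect_equal(concentration(0, 100, 15319), 0)
  expect_equal(concentration(200, 200, 15319),
               concentration(200, 100, 15319) / 2)
  expect_warning(v <- concentration(c(10, 10), c(5, 0), 15319), "zero marker")
  expect_true(is.na(v[2]) && !is.na(v[1]))

  expect_equal(influx(10000, 12.4), 806.4516, tolerance = 1e-4)
  expect_equal(influx(0, 12.4), 0)
  expect_equal(influx(500, 6.2), 2 * influx(500, 12.4))
  expect_error(influx(100, 0), "positive")
})

test_that("age-depth interpolation and deposition slopes", {
  ## a 810 cm core with basal age 9,978 cal BP: constant 12.32 yr/cm
  m <- age_depth_model(data.frame(depth_cm = c(0, 810),
                                  age_calBP = c(0, 9978)))
  ad <- age_and_deposition(m, c(100, 405, 810))
  expect_equal(ad$deposition_yr_cm, rep(9978 / 810, 3), tolerance = 1e-12)
  expect_equal(ad$age_calBP[3], 9978)                 # control point exact
  expect_equal(ad$age_calBP[1], 100 * 9978 / 810, tolerance = 1e-9)

  ## degenerate: uniform ages flagged
  flat <- age_depth_model(data.frame(depth_cm = c(0, 10),
                                     age_calBP = c(50, 50)))
  expect_warning(age_and_deposition(flat, 5), "zero deposition")

  ## extrapolation guard
  expect_error(age_and_deposition(m, 900), "extrapolate")
  expect_silent(age_and_deposition(m, 900, extrapolate = TRUE))

  ## monotone cubic stays monotone and hits the knots
  cp <- data.frame(depth_cm = c(0, 100, 300, 810),
                   age_calBP = c(0, 800, 3100, 9978))
  mc <- age_depth_model(cp, kind = "monotone")
  ad2 <- age_and_deposition(mc, cp$depth_cm)
  expect_equal(ad2$age_calBP, cp$age_calBP, tolerance = 1e-9)
  dense <- age_and_deposition(mc, seq(0, 810, by = 5))
  expect_true(all(diff(dense$age_calBP) >= -1e-9))

  expect_error(age_depth_model(data.frame(depth_cm = c(0, 10),
                                          age_calBP = c(100, 50))),
               "nondecreasing")
})

test_that("percentages follow the pollen-sum policy", {
  counts <- data.frame(sample_id = c("s1", "s2"), depth_cm = c(5, 10),
                       Betula = c(40, 0), Picea = c(60, 0),
                       "NPP/Minerals" = c(20, 30), Unknown = c(5, 5),
                       Eucalyptus = c(10, 12),
                       marker_count = c(10, 12), volume_cm3 = 1,
                       check.names = FALSE)
  expect_warning(p <- percentages(counts), "zero pollen sum")
  expect_equal(p$Betula[1] + p$Picea[1], 1)
  expect_equal(p$Betula[1], 0.4)
  expect_true(is.na(p$Betula[2]))
  ## excluded classes reported against total objects
  expect_equal(p[["NPP/Minerals_of_total"]][1], 20 / 135)
  ## one-class policy: that class is 100%
  p2 <- percentages(counts[1, ], pollen_sum_policy(include = "Betula"))
  expect_equal(p2$Betula, 1)
  expect_error(percentages(counts, pollen_sum_policy(include = "Nope")),
               "Nope")
})

test_that("constrained clustering reproduces hand-enumerated merge costs", {
  ## two identical samples merge at zero cost
  z0 <- coniss(rbind(c(1, 2), c(1, 2)), transform = "none")
  expect_equal(z0$merges$cost, 0)

  ## 1 variable, values (0, 0, 10, 10): costs 0, 0, 100
  z <- coniss(matrix(c(0, 0, 10, 10), 4, 1), transform = "none")
  expect_equal(sort(z$merges$cost[1:2]), c(0, 0))
  expect_equal(z$merges$cost[3], 100)
  expect_equal(z$total_dispersion, 100)
  ## cumulative dispersion is nondecreasing and conserved
  expect_true(all(diff(z$merges$cumulative) >= 0))
  tot <- sum(scale(matrix(c(0, 0, 10, 10)), scale = FALSE)^2)
  expect_equal(z$total_dispersion, tot)

  expect_error(coniss(matrix(1, 1, 2)), "2 samples")
  expect_error(coniss(matrix(1:4, 2, 2), depths = c(3, 3)), "monotone")
})

test_that("greedy merges equal the brute-force adjacent-pair argmin", {
  ## independent oracle: recompute every cluster dispersion from scratch
  oracle_step <- function(x, groups) {
    ids <- unique(groups)
    disp <- function(rows) {
      if (length(rows) == 1) return(0)
      sum(scale(x[rows, , drop = FALSE], scale = FALSE)^2)
    }
    costs <- vapply(seq_len(length(ids) - 1), function(j) {
      a <- which(groups == ids[j]); b <- which(groups == ids[j + 1])
      disp(c(a, b)) - disp(a) - disp(b)
    }, numeric(1))
    list(j = which.min(costs), cost = min(costs))
  }
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    x <- matrix(runif(n * 3), n, 3)
    z <- coniss(x, transform = "none")
    groups <- seq_len(n)
    for (step in seq_len(n - 1)) {
      o <- oracle_step(x, groups)
      expect_equal(z$merges$cost[step], o$cost, tolerance = 1e-9)
      ids <- unique(groups)
      groups[groups == ids[o$j + 1]] <- ids[o$j]
    }
  }
})

test_that("broken-stick expectations match the closed form", {
  expect_equal(broken_stick_expectation(2), c(0.75, 0.25))
  expect_equal(broken_stick_expectation(3),
               c(11 / 18, 5 / 18, 2 / 18), tolerance = 1e-12)
  for (m in c(2, 5, 17)) {
    e <- broken_stick_expectation(m)
    expect_equal(sum(e), 1, tolerance = 1e-12)
    expect_true(all(diff(e) < 0))
  }
})

test_that("zone boundaries cut the merge sequence into contiguous zones", {
  set.seed(33)
  x <- matrix(runif(12 * 4), 12, 4)
  z <- coniss(x, depths = seq(10, 120, by = 10))
  expect_equal(zone_boundaries(z, 1)$boundaries, integer(0))
  expect_equal(zone_boundaries(z, 12)$boundaries, 1:11)
  zb <- zone_boundaries(z, 4)
  expect_length(zb$boundaries, 3)
  members <- zone_membership(z, 4)
  expect_equal(length(unique(members)), 4)
  expect_true(all(diff(members) >= 0))   # contiguous zones in depth order
  expect_error(zone_boundaries(z, 0), "k must be")
})

test_that("a planted two-regime sequence recovers k = 2 at the changepoint", {
  set.seed(35)
  n <- 20
  depths <- seq(5, 100, by = 5)
  upper <- c(0.7, 0.2, 0.1); lower <- c(0.1, 0.2, 0.7)
  counts <- t(vapply(seq_len(n), function(i) {
    as.numeric(stats::rmultinom(1, 400,
                                if (i <= 10) upper else lower))
  }, numeric(3)))
  z <- broken_stick_zones(coniss(counts, depths = depths))
  expect_equal(z$k, 2L)
  ## boundary within one sample spacing of the true change (52.5 cm)
  expect_lte(abs(z$boundary_depths[1] - 52.5), 5)
})

test_that("structureless sequences usually carry no significant zones", {
  set.seed(37)
  ks <- vapply(1:30, function(r) {
    x <- matrix(runif(15 * 4), 15, 4)
    broken_stick_zones(coniss(x / rowSums(x), transform = "none"))$k
  }, integer(1))
  expect_gte(mean(ks == 1), 0.8)
})

test_that("diagram tables join percentages, concentration and influx", {
  counts <- data.frame(sample_id = c("s1", "s2"), depth_cm = c(100, 200),
                       Betula = c(80, 20), Picea = c(20, 80),
                       Eucalyptus = c(10, 10), "NPP/Minerals" = c(10, 30),
                       Unknown = c(0, 0),
                       marker_count = c(10, 10), volume_cm3 = 1,
                       check.names = FALSE)
  m <- age_depth_model(data.frame(depth_cm = c(0, 810),
                                  age_calBP = c(0, 9978)))
  tab <- diagram_table(counts, marker_added = 15319, age_model = m)
  b1 <- tab[tab$class == "Betula" & tab$sample_id == "s1", ]
  expect_equal(b1$percent, 80)
  expect_equal(b1$concentration, 80 * 15319 / 10)
  expect_equal(b1$influx, b1$concentration / (9978 / 810), tolerance = 1e-9)
})

test_that("generated sequences recover their composition within noise", {
  comp <- data.frame(depth_cm = c(10, 20, 30, 40),
                     Betula = 0.5, Picea = 0.3, Quercus = 0.2)
  fs <- generate_fossil_sequence(comp, n_objects = 500, marker_dose = 0,
                                 seed = 39)
  p <- count_proportions(fs$truth,
                         classes = c("Betula", "Picea", "Quercus"))
  ## binomial 99.9% envelope at n = 500
  for (cl in c("Betula", "Picea", "Quercus")) {
    tol <- 3.3 * sqrt(comp[[cl]][1] * (1 - comp[[cl]][1]) / 500)
    expect_true(all(abs(p[[cl]] - comp[[cl]][1]) <= tol))
  }
})
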