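# Circular statistics: axial doubling, summaries, and the four uniformity
# tests.

test_that("axial doubling maps opposite bearings onto one axis", {
  expect_equal(axial_double(orientation_sample(c(0, 180))), c(0, 0))
  expect_equal(axial_double(orientation_sample(45)), 90)
  s <- circular_mean_R(orientation_sample(c(90, 270, 90)))
  expect_equal(s$mean_axis_deg, c(90, 270))
  expect_equal(s$R, 1)
  expect_error(axial_double(orientation_sample(10, axial = FALSE)), "axial")
})

test_that("mean direction and resultant length match hand vector sums", {
  s <- circular_mean_R(orientation_sample(c(0, 90), axial = FALSE))
  expect_equal(s$mean_axis_deg, 45)
  expect_equal(s$R, sqrt(2) / 2)
  expect_equal(s$circ_variance, 1 - sqrt(2) / 2)
  all_same <- circular_mean_R(orientation_sample(rep(123, 7), axial = FALSE))
  expect_equal(all_same$R, 1)
  expect_equal(all_same$circ_variance, 0)
  sym <- circular_mean_R(orientation_sample(c(0, 90, 180, 270), axial = FALSE))
  expect_lt(sym$R, 1e-12)
})

test_that("angles are stored reduced modulo 360", {
  expect_equal(orientation_sample(c(370, -10))$angles_deg, c(10, 350))
})

test_that("the 95% confidence arc contains the mean direction when valid", {
  for (seed in 1:20) {
    s <- gen_orientations(40, kappa = 3, mean_axis_deg = 50, seed = seed)
    cs <- circular_mean_R(s)
    if (!cs$ci_valid) next
    lo <- cs$ci95_deg[1]; hi <- cs$ci95_deg[2]; mu <- cs$mean_axis_deg[1]
    inside <- if (lo <= hi) mu >= lo - 1e-9 && mu <= hi + 1e-9
              else mu >= lo - 1e-9 || mu <= hi + 1e-9
    expect_true(inside)
  }
})

test_that("rayleigh statistic and p behave at the extremes", {
  flat <- rayleigh_test(orientation_sample(c(0, 90, 180, 270), axial = FALSE))
  expect_lt(flat$statistic[["Z"]], 1e-12)
  expect_gt(flat$p_value, 0.99)
  peaked <- rayleigh_test(orientation_sample(rep(37, 50), axial = FALSE))
  expect_equal(peaked$statistic[["Z"]], 50)
  expect_lt(peaked$p_value, 1e-15)
  expect_error(rayleigh_test(orientation_sample(c(1, 2), axial = FALSE)),
               "n >= 4")
})

test_that("rao spacing statistic matches its definition at the extremes", {
  equi <- orientation_sample((0:49) * (360 / 50), axial = FALSE)
  expect_lt(rao_spacing_test(equi, n_sims = 50)$statistic[["U"]], 1e-9)
  same5 <- orientation_sample(rep(200, 5), axial = FALSE)
  expect_equal(rao_spacing_test(same5, n_sims = 50)$statistic[["U"]], 288)
})

test_that("rao table method brackets the Monte-Carlo p-value", {
  hits <- 0
  for (i in 1:40) {
    set.seed(3000 + i)
    s <- orientation_sample(runif(50, 0, 360), axial = FALSE)
    mc <- rao_spacing_test(s, method = "monte_carlo", n_sims = 2000,
                           seed = i)$p_value
    br <- rao_spacing_test(s, method = "table")$p_range
    hits <- hits + (mc >= br[1] && mc <= br[2])
  }
  expect_gte(hits / 40, 0.95)
})

test_that("watson U2 equals the definitional formula and is rotation invariant", {
  s <- orientation_sample(c(10, 100, 200, 300), axial = FALSE)
  got <- watson_u2_test(s)$statistic[["U2"]]
  # definitional oracle: centred squared deviations of uniform scores
  u <- sort(c(10, 100, 200, 300) / 360)
  n <- 4
  i <- 1:4
  oracle <- sum(((u - mean(u)) - ((2 * i - 1) / (2 * n) - 0.5))^2) + 1 / (12 * n)
  expect_equal(got, oracle)
  set.seed(5)
  ang <- runif(30, 0, 360)
  for (rot in c(37, 123.4, 291)) {
    expect_equal(
      watson_u2_test(orientation_sample((ang + rot) %% 360, axial = FALSE))$statistic[["U2"]],
      watson_u2_test(orientation_sample(ang, axial = FALSE))$statistic[["U2"]]
    )
  }
})

test_that("kuiper V is 1 for a single observation and rotation invariant", {
  v <- kuiper_test(orientation_sample(123, axial = FALSE),
                   method = "monte_carlo", n_sims = 20)
  expect_equal(v$statistic[["V"]], 1)
  set.seed(6)
  ang <- runif(25, 0, 360)
  base <- kuiper_test(orientation_sample(ang, axial = FALSE))$statistic[["V"]]
  for (rot in c(37, 200.5)) {
    expect_equal(
      kuiper_test(orientation_sample((ang + rot) %% 360, axial = FALSE))$statistic[["V"]],
      base
    )
  }
})

test_that("the axial pipeline is invariant to reflecting every bearing", {
  set.seed(11)
  ang <- runif(50, 0, 360)
  s1 <- orientation_sample(ang, axial = TRUE)
  s2 <- orientation_sample((360 - ang) %% 360, axial = TRUE)
  expect_equal(rayleigh_test(s1)$statistic[["Z"]],
               rayleigh_test(s2)$statistic[["Z"]])
  expect_equal(rao_spacing_test(s1, n_sims = 50)$statistic[["U"]],
               rao_spacing_test(s2, n_sims = 50)$statistic[["U"]])
  expect_equal(watson_u2_test(s1)$statistic[["U2"]],
               watson_u2_test(s2)$statistic[["U2"]])
  expect_equal(kuiper_test(s1)$statistic[["V"]],
               kuiper_test(s2)$statistic[["V"]])
})

test_that("Monte-Carlo p-values agree with the asymptotic approximations", {
  set.seed(21)
  s <- orientation_sample(runif(50, 0, 360), axial = FALSE)
  for (f in list(rayleigh_test, watson_u2_test)) {
    a <- f(s)$p_value
    m <- f(s, method = "monte_carlo", n_sims = 10000, seed = 2)$p_value
    expect_lt(abs(a - m), 0.02)
  }
  # the stabilized Kuiper series is designed for the tail; compare there
  set.seed(22)
  tail_s <- orientation_sample(rvm_test_sample <- runif(50, 0, 120),
                               axial = FALSE)
  a <- kuiper_test(tail_s)$p_value
  m <- kuiper_test(tail_s, method = "monte_carlo", n_sims = 10000,
                   seed = 2)$p_value
  expect_lt(a, 0.35)
  expect_lt(abs(a - m), 0.02)
  # p-values are probabilities everywhere
  for (seed in 1:10) {
    set.seed(seed)
    x <- orientation_sample(runif(30, 0, 360), axial = FALSE)
    ps <- c(rayleigh_test(x)$p_value,
            rao_spacing_test(x, n_sims = 200, seed = seed)$p_value,
            watson_u2_test(x)$p_value, kuiper_test(x)$p_value)
    expect_true(all(ps >= 0 & ps <= 1))
  }
})

test_that("rose bins conserve counts and honour axial double-plotting", {
  s <- orientation_sample(c(5, 15, 15, 200), axial = FALSE)
  rb <- rose_bins(s, 10)
  expect_equal(sum(rb$count), 4)
  expect_false(attr(rb, "double_plotted"))
  sa <- orientation_sample(c(5, 15, 15, 200), axial = TRUE)
  rba <- rose_bins(sa, 10)
  expect_equal(sum(rba$count), 8)
  expect_true(attr(rba, "double_plotted"))
  one_bin <- rose_bins(orientation_sample(c(41, 42, 43), axial = FALSE), 45)
  expect_equal(sum(one_bin$count > 0), 1)
  grid <- rose_bins(orientation_sample(0:359, axial = FALSE), 10)
  expect_true(all(grid$count == 10))
  expect_error(rose_bins(s, 7), "divisor")
})
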