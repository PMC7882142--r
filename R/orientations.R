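# Circular statistics for element-orientation data.
#
# Quarry-map orientations of elongate bones are axial: a bone aligned at 10
# degrees is indistinguishable from one at 190 degrees. Axial samples are
# therefore analyzed on the doubled circle (angle -> 2*angle mod 360), and
# mean directions are halved back and reported as a theta/theta+180 pair.
# Four one-sample uniformity tests are provided -- Rayleigh (unimodal
# alternatives), Rao's Spacing (multimodal-sensitive), Watson's U2 and
# Kuiper's (omnibus EDF tests) -- with asymptotic, table-bracket and seeded
# Monte-Carlo p-values. Angles are compass bearings in degrees, clockwise
# from north, stored in [0, 360); all trigonometry is done in radians.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Orientation sample
#'
#' @param angles_deg numeric vector of bearings in degrees; reduced modulo 360
#'   into `[0, 360)`.
#' @param axial logical; `TRUE` (default) for undirected line data (long axes
#'   of elements), `FALSE` for directed vectors.
#' @return an object of class `orientation_sample`.
#' @export
orientation_sample <- function(angles_deg, axial = TRUE) {
  if (!length(angles_deg) || !all(is.finite(angles_deg)))
    stopf("angles_deg must be a non-empty finite numeric vector")
  structure(
    list(angles_deg = angles_deg %% 360, axial = isTRUE(axial),
         n = length(angles_deg)),
    class = "orientation_sample"
  )
}

#' @export
print.orientation_sample <- function(x, ...) {
  cat(sprintf("orientation sample: n = %d, %s\n", x$n,
              if (x$axial) "axial (undirected)" else "directed"))
  invisible(x)
}

as_orientation_sample <- function(x, axial = TRUE) {
  if (inherits(x, "orientation_sample")) x else orientation_sample(x, axial)
}

#' Double axial angles onto the full circle
#'
#' Maps each angle to (2 * angle) mod 360, the standard device that turns
#' axial (period-180) data into ordinary circular data. Mean directions
#' computed on the doubled scale are halved back by [circular_mean_R()].
#'
#' @param sample an [orientation_sample()] with `axial = TRUE`, or a numeric
#'   vector of degrees.
#' @return numeric vector of doubled angles in `[0, 360)`.
#' @examples
#' axial_double(orientation_sample(c(0, 180))) # c(0, 0)
#' @export
axial_double <- function(sample) {
  s <- as_orientation_sample(sample)
  if (!s$axial) stopf("axial_double() requires an axial sample")
  (2 * s$angles_deg) %% 360
}

# angles on which the statistics operate: doubled for axial samples
working_angles <- function(sample, use_axial_doubling = TRUE) {
  s <- as_orientation_sample(sample)
  if (s$axial && use_axial_doubling) axial_double(s) else s$angles_deg
}

#' Mean direction, resultant length and 95% confidence interval
#'
#' Computes the mean resultant length R of the unit vectors, the mean
#' direction (for axial samples: on the doubled circle, halved back and
#' reported as a theta/theta+180 axis pair), circular variance 1 - R, and a
#' large-sample 95% confidence arc for the mean direction based on the
#' circular dispersion. The arc is `NA` (flagged full-circle) when the
#' dispersion-based half-width is undefined (arcsine argument above 1) or
#' when R is numerically zero.
#'
#' @param sample an [orientation_sample()] or numeric vector of degrees.
#' @param use_axial_doubling analyze axial samples on the doubled circle
#'   (default `TRUE`); `FALSE` treats the raw bearings as directed.
#' @return an object of class `circular_summary` with fields `mean_axis_deg`
#'   (length 2 for axial data), `R`, `circ_variance`, `ci95_deg`, `ci_valid`,
#'   `n`, `axial`.
#' @examples
#' circular_mean_R(orientation_sample(c(0, 90), axial = FALSE))$R # 0.7071
#' @export
circular_mean_R <- function(sample, use_axial_doubling = TRUE) {
  s <- as_orientation_sample(sample)
  doubled <- s$axial && use_axial_doubling
  w <- deg2rad(working_angles(s, use_axial_doubling))
  n <- s$n
  C <- mean(cos(w)); S <- mean(sin(w))
  R <- sqrt(C^2 + S^2)
  mu_w <- rad2deg(atan2(S, C)) %% 360

  ci <- c(NA_real_, NA_real_)
  ci_valid <- FALSE
  if (R > sqrt(.Machine$double.eps) && n >= 2) {
    # circular dispersion (second trigonometric moment about the mean)
    rho2 <- mean(cos(2 * (w - deg2rad(mu_w))))
    disp <- (1 - rho2) / (2 * R^2)
    arg <- stats::qnorm(0.975) * sqrt(disp / n)
    if (is.finite(arg) && arg <= 1) {
      half <- rad2deg(asin(arg))
      ci <- c(mu_w - half, mu_w + half) %% 360
      ci_valid <- TRUE
    }
  }

  if (doubled) {
    mu <- (mu_w / 2) %% 180
    mean_axis <- c(mu, mu + 180)
    if (ci_valid) ci <- (ci / 2) %% 180
  } else {
    mean_axis <- mu_w
  }

  structure(
    list(mean_axis_deg = mean_axis, R = R, circ_variance = 1 - R,
         ci95_deg = ci, ci_valid = ci_valid, n = n, axial = s$axial,
         doubled = doubled),
    class = "circular_summary"
  )
}

#' @export
print.circular_summary <- function(x, ...) {
  ax <- paste(sprintf("%.1f", x$mean_axis_deg), collapse = "/")
  cat(sprintf("circular summary (n = %d%s)\n", x$n,
              if (x$axial) ", axial" else ""))
  cat(sprintf("  mean %s: %s deg\n", if (x$axial) "axis" else "direction", ax))
  cat(sprintf("  R = %.4f, circular variance = %.4f\n", x$R, x$circ_variance))
  if (x$ci_valid)
    cat(sprintf("  95%% CI for mean: %.1f-%.1f deg\n",
                x$ci95_deg[1], x$ci95_deg[2]))
  else cat("  95% CI: undefined (dispersion too large)\n")
  invisible(x)
}

new_uniformity_test <- function(test_name, statistic, p_value, method,
                                n, p_range = NULL, n_sims = NULL, seed = NULL,
                                extra = list()) {
  structure(
    c(list(test_name = test_name, statistic = statistic,
           p_value = p_value, p_range = p_range, method = method,
           n = n, n_sims = n_sims, seed = seed), extra),
    class = "uniformity_test"
  )
}

#' @export
print.uniformity_test <- function(x, ...) {
  st <- paste(sprintf("%s = %.4g", names(x$statistic), x$statistic),
              collapse = ", ")
  cat(sprintf("%s (n = %d): %s\n", x$test_name, x$n, st))
  if (!is.null(x$p_range) && any(is.finite(x$p_range)))
    cat(sprintf("  %.3g > p > %.3g (%s)\n",
                x$p_range[2], x$p_range[1], x$method))
  else cat(sprintf("  p = %.4g (%s)\n", x$p_value, x$method))
  invisible(x)
}

# seeded Monte-Carlo p-value for an upper-tail statistic under the uniform null
mc_pvalue <- function(stat_fun, observed, n, n_sims, seed) {
  set.seed(substream_seed(seed, "montecarlo"))
  sims <- vapply(seq_len(n_sims),
                 function(i) stat_fun(stats::runif(n, 0, 360)), 0)
  (1 + sum(sims >= observed)) / (n_sims + 1)
}

#' Rayleigh test of circular uniformity
#'
#' Z = n * R^2, large for concentrated samples. The asymptotic p-value uses
#' the standard fourth-order series in Z and n; `method = "monte_carlo"`
#' simulates the null instead.
#'
#' @inheritParams circular_mean_R
#' @param method `"asymptotic"` (default) or `"monte_carlo"`.
#' @param n_sims,seed Monte-Carlo settings.
#' @return a `uniformity_test` object with statistics `Z` and `R`.
#' @export
rayleigh_test <- function(sample, use_axial_doubling = TRUE,
                          method = c("asymptotic", "monte_carlo"),
                          n_sims = 10000, seed = 20210211) {
  method <- match.arg(method)
  s <- as_orientation_sample(sample)
  w <- working_angles(s, use_axial_doubling)
  n <- s$n
  if (n < 4) stopf("Rayleigh test needs n >= 4")
  zstat <- function(deg) {
    r <- deg2rad(deg)
    length(r) * (mean(cos(r))^2 + mean(sin(r))^2)
  }
  Z <- zstat(w)
  R <- sqrt(Z / n)
  if (method == "asymptotic") {
    p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                      (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
    p <- min(max(p, 0), 1)
    new_uniformity_test("Rayleigh test", c(Z = Z, R = R), p, "asymptotic", n)
  } else {
    p <- mc_pvalue(zstat, Z, n, n_sims, seed)
    new_uniformity_test("Rayleigh test", c(Z = Z, R = R), p, "monte_carlo", n,
                        n_sims = n_sims, seed = seed)
  }
}

# Rao's Spacing U statistic (degrees)
rao_U_stat <- function(deg) {
  n <- length(deg)
  s <- sort(deg %% 360)
  sp <- c(diff(s), 360 - s[n] + s[1])
  0.5 * sum(abs(sp - 360 / n))
}

# Null quantiles of Rao's U (uniform null, degrees), frozen from a one-time
# simulation of 200,000 samples per n (seed 20210211; scripts in the package
# history). Rows: n; columns: upper-tail probability alpha (critical value =
# (1 - alpha) quantile). Used for table-bracket p-values.
rao_crit_table <- local({
  ns <- c(4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30, 35, 40, 45, 50,
          60, 70, 80, 90, 100, 125, 150, 200, 300, 500)
  alphas <- c(0.001, 0.005, 0.01, 0.05, 0.10, 0.25, 0.50, 0.90, 0.95, 0.99)
  vals <- c(
    247.141, 231.207, 221.252, 186.596, 168.290, 142.412, 111.804, 61.882, 49.049, 28.250,
    245.177, 222.846, 211.804, 183.497, 168.766, 142.689, 116.327, 70.099, 59.063, 39.823,
    234.274, 215.655, 206.416, 180.329, 166.090, 143.541, 118.879, 76.372, 65.804, 47.441,
    230.285, 211.854, 202.830, 177.979, 165.391, 143.838, 121.193, 81.451, 71.190, 53.728,
    223.896, 207.065, 198.708, 175.762, 163.615, 144.051, 122.634, 85.361, 75.595, 58.782,
    218.634, 203.161, 195.206, 173.760, 162.620, 143.734, 123.781, 88.415, 79.353, 63.370,
    216.106, 199.628, 192.432, 172.074, 161.393, 143.697, 124.822, 91.072, 82.261, 66.521,
    208.099, 194.865, 187.880, 169.146, 159.340, 143.273, 125.989, 95.110, 86.970, 72.087,
    203.840, 190.857, 183.839, 166.622, 157.600, 142.783, 126.886, 97.996, 90.322, 76.751,
    198.207, 186.361, 180.869, 164.835, 156.368, 142.570, 127.698, 100.700, 93.461, 80.142,
    195.490, 183.661, 178.192, 163.187, 155.288, 142.415, 128.201, 102.612, 95.747, 83.354,
    192.647, 181.416, 176.325, 161.916, 154.407, 142.080, 128.730, 104.261, 97.745, 85.907,
    186.361, 176.518, 171.779, 158.894, 152.299, 141.421, 129.371, 107.653, 101.657, 91.077,
    181.469, 172.858, 168.455, 156.757, 150.728, 140.817, 129.964, 110.022, 104.614, 94.469,
    177.388, 169.860, 165.861, 155.305, 149.636, 140.425, 130.320, 111.803, 106.740, 97.219,
    175.360, 167.286, 163.690, 153.837, 148.636, 139.970, 130.564, 113.113, 108.369, 99.651,
    172.270, 165.359, 161.981, 152.752, 147.836, 139.677, 130.834, 114.370, 109.904, 101.558,
    170.143, 163.536, 160.461, 151.711, 147.108, 139.388, 130.934, 115.435, 111.135, 103.127,
    167.260, 160.973, 157.989, 150.077, 145.843, 138.893, 131.218, 116.987, 113.137, 105.871,
    164.654, 158.987, 156.343, 148.841, 144.945, 138.465, 131.376, 118.156, 114.510, 107.696,
    162.997, 157.367, 154.758, 147.836, 144.215, 138.147, 131.501, 119.201, 115.815, 109.521,
    160.371, 155.871, 153.518, 147.027, 143.577, 137.851, 131.559, 119.957, 116.738, 110.764,
    159.497, 154.841, 152.448, 146.307, 143.001, 137.574, 131.675, 120.629, 117.548, 111.790,
    156.368, 152.315, 150.325, 144.859, 141.958, 137.148, 131.847, 121.889, 119.097, 113.893,
    154.525, 150.632, 148.778, 143.809, 141.194, 136.781, 131.949, 122.855, 120.318, 115.678,
    151.567, 148.286, 146.712, 142.413, 140.101, 136.282, 132.098, 124.234, 122.046, 118.018,
    147.842, 145.326, 144.104, 140.576, 138.715, 135.630, 132.234, 125.761, 123.939, 120.566,
    144.697, 142.462, 141.512, 138.803, 137.351, 134.952, 132.292, 127.300, 125.881, 123.283
  )
  m <- matrix(vals, nrow = length(ns), ncol = length(alphas), byrow = TRUE,
              dimnames = list(ns, alphas))
  list(ns = ns, alphas = alphas, crit = m)
})

# critical values for sample size n, interpolated linearly in n
rao_crit_for_n <- function(n) {
  tb <- rao_crit_table
  if (n <= min(tb$ns)) return(tb$crit[1, ])
  if (n >= max(tb$ns)) return(tb$crit[nrow(tb$crit), ])
  i <- findInterval(n, tb$ns)
  w <- (n - tb$ns[i]) / (tb$ns[i + 1] - tb$ns[i])
  (1 - w) * tb$crit[i, ] + w * tb$crit[i + 1, ]
}

#' Rao's Spacing test of circular uniformity
#'
#' U = 1/2 * sum |T_i - lambda| over the circular spacings T_i of the sorted
#' angles (the circle closed by the wrap-around spacing), lambda = 360/n; U is
#' 0 for perfectly equispaced angles and large for clustered ones. The default
#' p-value is a seeded Monte-Carlo estimate; `method = "table"` returns a
#' bracketing range between conventional significance levels, interpolated in
#' a simulated critical-value grid (200,000 null samples per tabulated n).
#'
#' @inheritParams rayleigh_test
#' @param method `"monte_carlo"` (default) or `"table"`.
#' @return a `uniformity_test` object with statistic `U` (degrees); for the
#'   table method `p_range = c(low, high)` brackets the p-value.
#' @export
rao_spacing_test <- function(sample, use_axial_doubling = TRUE,
                             method = c("monte_carlo", "table"),
                             n_sims = 10000, seed = 20210211) {
  method <- match.arg(method)
  s <- as_orientation_sample(sample)
  w <- working_angles(s, use_axial_doubling)
  n <- s$n
  if (n < 4) stopf("Rao's Spacing test needs n >= 4")
  U <- rao_U_stat(w)
  if (method == "monte_carlo") {
    p <- mc_pvalue(rao_U_stat, U, n, n_sims, seed)
    new_uniformity_test("Rao's Spacing test", c(U = U), p, "monte_carlo", n,
                        n_sims = n_sims, seed = seed)
  } else {
    crit <- rao_crit_for_n(n)           # critical values, alpha ascending
    alphas <- rao_crit_table$alphas
    # U >= crit[alpha] means p <= alpha; crit is decreasing in alpha
    below <- which(U >= crit)           # alphas whose critical value U reaches
    hi <- if (length(below)) alphas[min(below)] else 1
    lo <- if (length(below) && min(below) > 1) alphas[min(below) - 1] else
      if (length(below)) 0 else alphas[length(alphas)]
    new_uniformity_test("Rao's Spacing test", c(U = U),
                        p_value = mean(c(lo, hi)), method = "table", n,
                        p_range = c(lo, hi))
  }
}

# Watson's U2 statistic on angles in degrees
watson_u2_stat <- function(deg) {
  n <- length(deg)
  u <- sort((deg %% 360) / 360)
  i <- seq_len(n)
  sum((u - (2 * i - 1) / (2 * n))^2) - n * (mean(u) - 0.5)^2 + 1 / (12 * n)
}

#' Watson's U2 test of circular uniformity
#'
#' The rotation-invariant Cramer-von Mises statistic for the circle. The
#' asymptotic p-value applies the standard series to the small-sample
#' modified statistic (U2 - 0.1/n + 0.1/n^2) * (1 + 0.8/n).
#'
#' @inheritParams rayleigh_test
#' @return a `uniformity_test` object with statistics `U2` and `U2_mod`.
#' @export
watson_u2_test <- function(sample, use_axial_doubling = TRUE,
                           method = c("asymptotic", "monte_carlo"),
                           n_sims = 10000, seed = 20210211) {
  method <- match.arg(method)
  s <- as_orientation_sample(sample)
  w <- working_angles(s, use_axial_doubling)
  n <- s$n
  if (n < 4) stopf("Watson's U2 test needs n >= 4")
  U2 <- watson_u2_stat(w)
  U2m <- (U2 - 0.1 / n + 0.1 / n^2) * (1 + 0.8 / n)
  if (method == "asymptotic") {
    k <- 1:50
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * U2m))
    p <- min(max(p, 0), 1)
    new_uniformity_test("Watson's U2 test", c(U2 = U2, U2_mod = U2m), p,
                        "asymptotic", n)
  } else {
    p <- mc_pvalue(watson_u2_stat, U2, n, n_sims, seed)
    new_uniformity_test("Watson's U2 test", c(U2 = U2, U2_mod = U2m), p,
                        "monte_carlo", n, n_sims = n_sims, seed = seed)
  }
}

# Kuiper's raw V statistic on angles in degrees
kuiper_v_stat <- function(deg) {
  n <- length(deg)
  u <- sort((deg %% 360) / 360)
  i <- seq_len(n)
  max(i / n - u) + max(u - (i - 1) / n)
}

#' Kuiper's test of circular uniformity
#'
#' V = D+ + D- against the uniform CDF on the circle; rotation invariant.
#' Both the raw statistic and the stabilized statistic
#' V * (sqrt(n) + 0.155 + 0.24/sqrt(n)) are reported; the asymptotic p-value
#' uses the standard series on the stabilized scale.
#'
#' @inheritParams rayleigh_test
#' @return a `uniformity_test` object with statistics `V` (raw) and
#'   `V_stabilized`.
#' @export
kuiper_test <- function(sample, use_axial_doubling = TRUE,
                        method = c("asymptotic", "monte_carlo"),
                        n_sims = 10000, seed = 20210211) {
  method <- match.arg(method)
  s <- as_orientation_sample(sample)
  w <- working_angles(s, use_axial_doubling)
  n <- s$n
  if (n < 1) stopf("empty sample")
  if (method == "asymptotic" && n < 4)
    stopf("Kuiper's asymptotic p-value needs n >= 4")
  V <- kuiper_v_stat(w)
  K <- V * (sqrt(n) + 0.155 + 0.24 / sqrt(n))
  if (method == "asymptotic") {
    k <- 1:50
    p <- 2 * sum((4 * k^2 * K^2 - 1) * exp(-2 * k^2 * K^2))
    p <- min(max(p, 0), 1)
    new_uniformity_test("Kuiper's test", c(V = V, V_stabilized = K), p,
                        "asymptotic", n)
  } else {
    p <- mc_pvalue(kuiper_v_stat, V, n, n_sims, seed)
    new_uniformity_test("Kuiper's test", c(V = V, V_stabilized = K), p,
                        "monte_carlo", n, n_sims = n_sims, seed = seed)
  }
}

#' Run the full uniformity-test battery
#'
#' Convenience wrapper returning the circular summary plus all four tests,
#' as reported in quarry-map taphonomic analyses.
#'
#' @inheritParams rayleigh_test
#' @param rao_method p-value method for [rao_spacing_test()].
#' @return a list with elements `summary`, `rayleigh`, `rao`, `watson`,
#'   `kuiper`.
#' @export
orientation_battery <- function(sample, use_axial_doubling = TRUE,
                                rao_method = "monte_carlo",
                                n_sims = 10000, seed = 20210211) {
  s <- as_orientation_sample(sample)
  list(
    summary = circular_mean_R(s, use_axial_doubling),
    rayleigh = rayleigh_test(s, use_axial_doubling),
    rao = rao_spacing_test(s, use_axial_doubling, method = rao_method,
                           n_sims = n_sims, seed = seed),
    watson = watson_u2_test(s, use_axial_doubling),
    kuiper = kuiper_test(s, use_axial_doubling)
  )
}

#' Rose-diagram bin counts
#'
#' Counts angles into sectors of `bin_width_deg`. For axial samples the
#' counts are the conventional double-plotted display: each datum is counted
#' in both its theta and theta+180 sectors (so counts sum to 2n); this is
#' display-only and flagged in the result.
#'
#' @param sample an [orientation_sample()] or numeric vector of degrees.
#' @param bin_width_deg sector width; must divide 360.
#' @return a data frame with `bin_low`, `bin_high`, `count`, and attribute
#'   `double_plotted`.
#' @export
rose_bins <- function(sample, bin_width_deg = 10) {
  s <- as_orientation_sample(sample)
  if (bin_width_deg <= 0 || 360 %% bin_width_deg != 0)
    stopf("bin_width_deg must be a positive divisor of 360")
  ang <- s$angles_deg
  if (s$axial) ang <- c(ang, (ang + 180) %% 360)
  edges <- seq(0, 360, bin_width_deg)
  idx <- floor(ang / bin_width_deg) + 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  out <- data.frame(bin_low = utils::head(edges, -1), bin_high = edges[-1],
                    count = counts)
  attr(out, "double_plotted") <- s$axial
  out
}
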