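# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes: triaxial clast populations with a controllable
# shape-class mix, axial angle samples (uniform or von Mises-concentrated),
# discrete character matrices evolved on a known tree, and decomposed
# skeletons with known true body length. Every generator takes an explicit
# seed and derives a private substream from it, so adding one generator never
# perturbs another's output.

#' Simulate a clast population
#'
#' Draws the long axis from a log-normal, then the b/a and c/b ratios from
#' scaled Beta(2, 2) distributions whose supports lie strictly inside the
#' Zingg region of the class drawn from `mix`, so every simulated clast is
#' classified into its intended class by construction. Mass is a density x
#' ellipsoid-volume proxy (pi/6 * a * b * c).
#'
#' @param n number of clasts.
#' @param mix named class probabilities over disk/sphere/blade/roller,
#'   summing to 1. The default mirrors a beach-dominated gastrolith
#'   population: 65.8% disks and 13.2% spheres, the remainder split evenly.
#' @param seed integer seed.
#' @param a_meanlog,a_sdlog log-normal parameters of the a axis (mm).
#' @param density_g_cm3 clast density (quartzite/chert-like default).
#' @param lithologies labels sampled uniformly for the lithology field.
#' @return list of [clast()] objects.
#' @export
gen_clasts <- function(n = 76,
                       mix = c(disk = 0.658, sphere = 0.132,
                               blade = 0.105, roller = 0.105),
                       seed = 20210211,
                       a_meanlog = log(18), a_sdlog = 0.45,
                       density_g_cm3 = 2.65,
                       lithologies = c("chert", "quartzite")) {
  classes <- c("disk", "sphere", "blade", "roller")
  if (!all(names(mix) %in% classes) || any(mix < 0))
    stopf("mix must be non-negative weights over %s",
          paste(classes, collapse = "/"))
  mix <- mix[classes]
  mix[is.na(mix)] <- 0
  names(mix) <- classes
  if (abs(sum(mix) - 1) > 1e-6) stopf("mix must sum to 1")
  set.seed(substream_seed(seed, "clasts"))
  cls <- sample(classes, n, replace = TRUE, prob = mix)
  a <- stats::rlnorm(n, a_meanlog, a_sdlog)
  rbeta_in <- function(k, lo, hi) lo + (hi - lo) * stats::rbeta(k, 2, 2)
  # Zingg regions at the 2/3 threshold, shrunk by a small margin
  lohi <- list(
    disk   = list(ba = c(0.68, 0.99), cb = c(0.20, 0.65)),
    sphere = list(ba = c(0.68, 0.99), cb = c(0.68, 0.99)),
    blade  = list(ba = c(0.30, 0.65), cb = c(0.20, 0.65)),
    roller = list(ba = c(0.30, 0.65), cb = c(0.68, 0.99))
  )
  lapply(seq_len(n), function(i) {
    r <- lohi[[cls[i]]]
    b <- a[i] * rbeta_in(1, r$ba[1], r$ba[2])
    cc <- b * rbeta_in(1, r$cb[1], r$cb[2])
    mass <- density_g_cm3 * (pi / 6) * a[i] * b * cc / 1000
    # recorded to balance precision, as a field scale would (0.1 g floor)
    clast(a[i], b, cc, mass_g = max(0.1, round(mass, 1)),
          lithology = sample(lithologies, 1),
          id = sprintf("G%03d", i))
  })
}

# von Mises sampler (Best & Fisher acceptance-rejection); degrees
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  mu <- deg2rad(mu_deg)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  rad2deg(out) %% 360
}

#' Simulate an orientation sample
#'
#' `kappa = 0` gives circular-uniform bearings. For `kappa > 0` the sample is
#' von Mises on the doubled circle around `2 * mean_axis_deg` and halved back
#' to axial bearings (each datum assigned to one end of its axis at random),
#' the generative counterpart of the angle-doubling analysis.
#'
#' @param n sample size.
#' @param kappa von Mises concentration (>= 0) on the doubled scale.
#' @param mean_axis_deg axis of concentration.
#' @param seed integer seed.
#' @param axial return an axial sample (default) or directed vectors.
#' @return an [orientation_sample()].
#' @export
gen_orientations <- function(n = 50, kappa = 0, mean_axis_deg = 90,
                             seed = 20210211, axial = TRUE) {
  if (kappa < 0) stopf("kappa must be >= 0")
  set.seed(substream_seed(seed, "orientations"))
  if (!axial) {
    ang <- if (kappa == 0) stats::runif(n, 0, 360) else
      rvonmises_deg(n, mean_axis_deg, kappa)
    return(orientation_sample(ang, axial = FALSE))
  }
  doubled <- if (kappa == 0) stats::runif(n, 0, 360) else
    rvonmises_deg(n, (2 * mean_axis_deg) %% 360, kappa)
  axis <- doubled / 2                       # in [0, 180)
  flip <- stats::runif(n) < 0.5
  orientation_sample((axis + 180 * flip) %% 360, axial = TRUE)
}

#' Evolve a character matrix on a known tree
#'
#' Each character evolves root-to-tip under a symmetric k-state model: along
#' every edge the state changes with probability `change_prob`, moving to one
#' of the other states uniformly. Optional per-cell missingness replaces
#' scorings with `?`.
#'
#' @param n_taxa taxa count (ignored when `tree` is supplied).
#' @param n_chars characters to simulate.
#' @param n_states state count (>= 2); symbols are `0, 1, ...`.
#' @param change_prob per-edge change probability in `[0, 1]`.
#' @param missing_prob per-cell probability of a missing scoring.
#' @param seed integer seed.
#' @param tree optional rooted binary [ape::phylo] to evolve on.
#' @return list with `matrix` (a [character_matrix()]) and `tree` (the true
#'   tree, returned unrooted as the search target).
#' @export
gen_matrix_on_tree <- function(n_taxa = 12, n_chars = 60, n_states = 2,
                               change_prob = 0.1, missing_prob = 0,
                               seed = 20210211, tree = NULL) {
  if (change_prob < 0 || change_prob > 1)
    stopf("change_prob must lie in [0, 1]")
  if (missing_prob < 0 || missing_prob > 1)
    stopf("missing_prob must lie in [0, 1]")
  if (n_states < 2) stopf("n_states must be >= 2")
  set.seed(substream_seed(seed, "matrix"))
  if (is.null(tree)) {
    tree <- ape::rtree(n_taxa, br = NULL,
                       tip.label = sprintf("t%02d", seq_len(n_taxa)))
  }
  if (!ape::is.binary(tree)) stopf("tree must be binary")
  rtree <- if (ape::is.rooted(tree)) tree else
    ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  ntip <- length(rtree$tip.label)
  E <- rtree$edge
  root <- setdiff(E[, 1], E[, 2])
  # preorder so parents are assigned before children
  pre <- rev(postorder_edges(rtree))
  states <- matrix(0L, max(E), n_chars)
  states[root, ] <- sample.int(n_states, n_chars, replace = TRUE) - 1L
  for (e in pre) {
    p <- E[e, 1]; ch <- E[e, 2]
    flip <- stats::runif(n_chars) < change_prob
    s <- states[p, ]
    if (any(flip)) {
      shift <- sample.int(n_states - 1L, sum(flip), replace = TRUE)
      s[flip] <- (s[flip] + shift) %% n_states
    }
    states[ch, ] <- s
  }
  cells <- matrix(as.character(states[seq_len(ntip), , drop = FALSE]),
                  ntip, n_chars)
  if (missing_prob > 0)
    cells[stats::runif(length(cells)) < missing_prob] <- "?"
  cm <- character_matrix(rtree$tip.label, cells,
                         symbols = as.character(seq_len(n_states) - 1L))
  list(matrix = cm, tree = ape::unroot(rtree))
}

#' Decompose a synthetic skeleton into body-size-estimation inputs
#'
#' Builds a "true" skeleton (neck, trunk, caudal series, skull), then emits
#' the specimen measurements and a comparative-proportion table whose
#' fractions equal the true ones perturbed by multiplicative log-normal
#' noise. True fractions are drawn on a 0.001 grid so the 3-decimal
#' proportion table is lossless at zero noise and [estimate_body_size()]
#' inverts the construction exactly up to its reporting rounding.
#'
#' @param seed integer seed.
#' @param trunk_mm true trunk (pectoral-sacral) length.
#' @param caudal_fraction true caudal / post-cervical fraction (3 decimals).
#' @param neck_fraction true neck / postcranial fraction (3 decimals).
#' @param skull_mm true skull length.
#' @param noise_sd sd of the log-normal multiplicative noise on fractions.
#' @param n_per_kind number of comparative entries emitted per part kind.
#' @param preserved_caudal_fraction fraction of the true caudal series
#'   "preserved" in the specimen record.
#' @return list with `spec` ([specimen_measurements()]), `props` (list of
#'   [comparative_proportion()]), and `true_total_m`.
#' @export
gen_specimen_proportions <- function(seed = 20210211, trunk_mm = 1400,
                                     caudal_fraction = 0.35,
                                     neck_fraction = 0.5,
                                     skull_mm = 300, noise_sd = 0,
                                     n_per_kind = 2,
                                     preserved_caudal_fraction = 0.5) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (caudal_fraction <= 0 || caudal_fraction >= 1 ||
      neck_fraction <= 0 || neck_fraction >= 1)
    stopf("fractions must lie strictly inside (0, 1)")
  set.seed(substream_seed(seed, "skeleton"))
  caudal_fraction <- round_half_up(caudal_fraction, 3)
  neck_fraction <- round_half_up(neck_fraction, 3)
  caudal_mm <- caudal_fraction * trunk_mm / (1 - caudal_fraction)
  postcervical_mm <- trunk_mm + caudal_mm
  postcranial_mm <- postcervical_mm / (1 - neck_fraction)
  true_total_m <- (postcranial_mm + skull_mm) / 1000

  noisy_frac <- function(f) {
    if (noise_sd == 0) return(f)
    g <- f * stats::rlnorm(1, 0, noise_sd)
    round_half_up(min(max(g, 0.01), 0.95), 3)
  }
  mk <- function(kind, f, i) {
    fr <- noisy_frac(f)
    whole <- 100000
    comparative_proportion(sprintf("sim_%s_%d", kind, i), kind,
                           fr * whole, whole)
  }
  props <- c(
    lapply(seq_len(n_per_kind), function(i)
      mk("caudal_of_postcervical", caudal_fraction, i)),
    lapply(seq_len(n_per_kind), function(i)
      mk("neck_of_postcranial", neck_fraction, i))
  )
  spec <- specimen_measurements(
    trunk_mm = trunk_mm,
    preserved_caudal_mm = max(1, preserved_caudal_fraction * caudal_mm),
    skull_mm = skull_mm,
    scale_ratio_to_largest = 1
  )
  list(spec = spec, props = props, true_total_m = true_total_m)
}

#' Write the default fixture set
#'
#' Regenerates the committed example inputs: a 76-clast table with a
#' beach-like shape mix, 50 near-uniform axial angles, a 12-taxon
#' 60-character matrix evolved on a known tree (with its true tree in
#' Newick), and the reference comparative-proportion table.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return the directory, invisibly.
#' @export
write_default_fixtures <- function(dir, seed = 20210211) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_clast_table(gen_clasts(76, seed = seed),
                    file.path(dir, "clasts.csv"))
  write_angle_table(gen_orientations(50, kappa = 0, seed = seed),
                    file.path(dir, "angles.csv"))
  sim <- gen_matrix_on_tree(12, 60, 2, change_prob = 0.15, seed = seed)
  write_nexus(sim$matrix, file.path(dir, "matrix.nex"))
  write_newick(sim$tree, file.path(dir, "true_tree.nwk"))
  utils::write.csv(reference_proportions(as_data_frame = TRUE),
                   file.path(dir, "proportions.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
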