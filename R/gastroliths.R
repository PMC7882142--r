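# Clast (gastrolith) shape and mass statistics.
#
# Shape indices follow the triaxial tradition of sedimentary petrology:
# a >= b >= c are the maximum, intermediate and minimum orthogonal axes.
# Maximum Projection Sphericity psi = (c^2/(a*b))^(1/3) measures how closely
# the clast's maximum projection area approaches that of a sphere of equal
# volume; the Oblate-Prolate index OP = (10/(c/a)) * ((a-b)/(a-c) - 0.5) is
# negative for disk-tending (oblate) and positive for rod-tending (prolate)
# clasts. Populations of both indices discriminate beach from river gravels.

#' Construct a clast from triaxial measurements
#'
#' Axes are sorted on construction, so measurement columns may come in any
#' order.
#'
#' @param a,b,c axis lengths in mm (any order; sorted to a >= b >= c).
#' @param mass_g optional mass in grams.
#' @param lithology optional lithology label.
#' @param id optional identifier.
#' @return an object of class `clast`.
#' @examples
#' clast(10, 20, 5) # stored as a=20, b=10, c=5
#' @export
clast <- function(a, b, c, mass_g = NA_real_, lithology = NA_character_,
                  id = NA_character_) {
  ax <- sort(c(a, b, c), decreasing = TRUE)
  if (!all(is.finite(ax)) || any(ax <= 0))
    stopf("all three axes must be positive finite numbers")
  if (!is.na(mass_g) && mass_g <= 0) stopf("mass_g must be positive")
  structure(
    list(a = ax[1], b = ax[2], c = ax[3], mass_g = mass_g,
         lithology = lithology, id = id),
    class = "clast"
  )
}

#' @export
print.clast <- function(x, ...) {
  cat(sprintf("clast %s: a=%g b=%g c=%g mm%s\n",
              ifelse(is.na(x$id), "", x$id), x$a, x$b, x$c,
              ifelse(is.na(x$mass_g), "", sprintf(", %g g", x$mass_g))))
  invisible(x)
}

#' Maximum Projection Sphericity
#'
#' psi = (c^2 / (a * b))^(1/3); equals 1 only for a perfect sphere (a = b = c)
#' and is invariant under uniform rescaling of the axes.
#'
#' @param x a [clast()].
#' @return psi in (0, 1].
#' @examples
#' sphericity(clast(20, 10, 5)) # 0.5
#' @export
sphericity <- function(x) {
  stopifnot(inherits(x, "clast"))
  (x$c^2 / (x$a * x$b))^(1 / 3)
}

#' Oblate-Prolate index
#'
#' OP = (10 / (c/a)) * ((a - b)/(a - c) - 0.5). Undefined for equant clasts
#' (a = c), for which `NA` is returned; [summarize_clasts()] excludes and
#' counts these.
#'
#' @param x a [clast()].
#' @return the OP index, or `NA_real_` when a = c.
#' @examples
#' oblate_prolate(clast(20, 10, 5)) # 6.667
#' @export
oblate_prolate <- function(x) {
  stopifnot(inherits(x, "clast"))
  if (x$a == x$c) return(NA_real_)
  (10 / (x$c / x$a)) * ((x$a - x$b) / (x$a - x$c) - 0.5)
}

#' Four-class clast shape assignment
#'
#' The default `"zingg"` scheme partitions the (b/a, c/b) plane at 2/3:
#' both ratios >= 2/3 gives a sphere (equant), only b/a >= 2/3 a disk
#' (oblate), only c/b >= 2/3 a roller (cylindrical/prolate), neither a blade.
#' The alternative `"form_triangle"` scheme classifies on the (c/a,
#' (a-b)/(a-c)) form triangle: compact clasts (c/a >= 2/3) are spheres,
#' otherwise the disk/blade/roller decision is by thirds of the elongation
#' coordinate (a-b)/(a-c) (equant degenerate clasts with a = c are spheres).
#' Both schemes are exhaustive and exclusive.
#'
#' @param x a [clast()].
#' @param scheme `"zingg"` (default) or `"form_triangle"`.
#' @return one of `"disk"`, `"sphere"`, `"blade"`, `"roller"`.
#' @examples
#' classify_shape(clast(10, 9, 8)) # "sphere"
#' classify_shape(clast(10, 9, 3)) # "disk"
#' @export
classify_shape <- function(x, scheme = c("zingg", "form_triangle")) {
  stopifnot(inherits(x, "clast"))
  scheme <- match.arg(scheme)
  thr <- 2 / 3
  if (scheme == "zingg") {
    ba <- x$b / x$a
    cb <- x$c / x$b
    if (ba >= thr) {
      if (cb >= thr) "sphere" else "disk"
    } else {
      if (cb >= thr) "roller" else "blade"
    }
  } else {
    if (x$c / x$a >= thr) return("sphere")
    e <- (x$a - x$b) / (x$a - x$c) # a > c guaranteed since c/a < 2/3
    if (e < 1 / 3) "disk" else if (e > 2 / 3) "roller" else "blade"
  }
}

#' Summarize a clast population
#'
#' Computes per-clast shape indices and aggregates them: sample means and
#' standard deviations (n - 1 denominator) of psi and OP, shape-class
#' percentages, mass statistics and a fixed-width mass histogram. Clasts with
#' undefined OP (a = c) are excluded from the OP mean/sd and counted in
#' `n_op_excluded`; mass statistics use only clasts with a recorded mass.
#'
#' @param clasts a non-empty list of [clast()] objects.
#' @param mass_bin_width_g histogram bin width in grams (bins start at 0).
#' @param scheme shape scheme passed to [classify_shape()].
#' @return an object of class `gastrolith_summary`.
#' @examples
#' s <- summarize_clasts(list(clast(20, 10, 5, mass_g = 3)))
#' s$mean_psi # 0.5
#' @export
summarize_clasts <- function(clasts, mass_bin_width_g = 2,
                             scheme = c("zingg", "form_triangle")) {
  scheme <- match.arg(scheme)
  if (!length(clasts) || !all(vapply(clasts, inherits, TRUE, "clast")))
    stopf("clasts must be a non-empty list of clast objects")
  if (mass_bin_width_g <= 0) stopf("mass_bin_width_g must be positive")
  n <- length(clasts)
  psi <- vapply(clasts, sphericity, 0)
  op <- vapply(clasts, oblate_prolate, 0)
  cls <- vapply(clasts, classify_shape, "", scheme = scheme)
  op_ok <- !is.na(op)
  n_excl <- sum(!op_ok)
  if (n_excl > 0)
    message(n_excl, " equant clast(s) (a = c) excluded from OP statistics")

  sd_or_na <- function(v) if (length(v) > 1) stats::sd(v) else NA_real_
  classes <- c("disk", "sphere", "blade", "roller")
  pct <- 100 * as.vector(table(factor(cls, levels = classes))) / n
  names(pct) <- classes

  mass <- vapply(clasts, `[[`, 0, "mass_g")
  mass <- mass[!is.na(mass)]
  if (length(mass)) {
    edges <- seq(0, mass_bin_width_g *
                   ceiling(max(mass) / mass_bin_width_g), mass_bin_width_g)
    counts <- as.vector(table(cut(mass, edges, right = TRUE,
                                  include.lowest = TRUE)))
    mass_stats <- list(n = length(mass), min = min(mass), max = max(mass),
                       mean = mean(mass), total = sum(mass),
                       bin_edges = edges, bin_counts = counts)
  } else {
    mass_stats <- list(n = 0L, min = NA_real_, max = NA_real_,
                       mean = NA_real_, total = NA_real_,
                       bin_edges = numeric(), bin_counts = integer())
  }

  structure(
    list(
      n = n, scheme = scheme,
      mean_psi = mean(psi), sd_psi = sd_or_na(psi),
      mean_op = if (any(op_ok)) mean(op[op_ok]) else NA_real_,
      sd_op = if (sum(op_ok) > 1) stats::sd(op[op_ok]) else NA_real_,
      n_op_excluded = n_excl,
      class_percentages = pct,
      mass = mass_stats,
      indices = data.frame(
        id = vapply(clasts, function(k) as.character(k$id %||% NA), ""),
        a = vapply(clasts, `[[`, 0, "a"),
        b = vapply(clasts, `[[`, 0, "b"),
        c = vapply(clasts, `[[`, 0, "c"),
        psi = psi, op = op, shape_class = cls,
        stringsAsFactors = FALSE
      )
    ),
    class = "gastrolith_summary"
  )
}

#' @export
print.gastrolith_summary <- function(x, ...) {
  cat(sprintf("Gastrolith summary (n = %d, %s scheme)\n", x$n, x$scheme))
  cat(sprintf("  psi: mean %.2f (sd %.2f)\n", x$mean_psi,
              ifelse(is.na(x$sd_psi), NA, x$sd_psi)))
  cat(sprintf("  OP:  mean %.2f (sd %.2f)%s\n", x$mean_op, x$sd_op,
              if (x$n_op_excluded) sprintf(" [%d equant excluded]",
                                           x$n_op_excluded) else ""))
  cat("  shape classes (%): ",
      paste(sprintf("%s %.1f", names(x$class_percentages),
                    x$class_percentages), collapse = ", "), "\n", sep = "")
  if (x$mass$n)
    cat(sprintf("  mass: %g-%g g, mean %.1f g, total %.1f g (n = %d)\n",
                x$mass$min, x$mass$max, x$mass$mean, x$mass$total, x$mass$n))
  invisible(x)
}

#' Plot-data exports for a clast population
#'
#' Returns the coordinates behind the standard population panels: a mass
#' histogram, the b/a vs c/b shape scatter, a psi histogram, the class
#' percentages, and the (mean psi, mean OP) point used for visual comparison
#' against published depositional-environment fields (no environment label is
#' assigned).
#'
#' @param summary a [summarize_clasts()] result.
#' @param psi_bin_width bin width for the psi histogram.
#' @return a named list of data frames.
#' @export
clast_plot_data <- function(summary, psi_bin_width = 0.05) {
  stopifnot(inherits(summary, "gastrolith_summary"))
  idx <- summary$indices
  psi_edges <- seq(0, 1, psi_bin_width)
  list(
    mass_histogram = if (summary$mass$n) data.frame(
      bin_low = utils::head(summary$mass$bin_edges, -1),
      bin_high = summary$mass$bin_edges[-1],
      count = summary$mass$bin_counts
    ) else data.frame(bin_low = numeric(), bin_high = numeric(),
                      count = integer()),
    shape_scatter = data.frame(id = idx$id, b_over_a = idx$b / idx$a,
                               c_over_b = idx$c / idx$b,
                               shape_class = idx$shape_class),
    psi_histogram = data.frame(
      bin_low = utils::head(psi_edges, -1), bin_high = psi_edges[-1],
      count = as.vector(table(cut(idx$psi, psi_edges, right = TRUE,
                                  include.lowest = TRUE)))
    ),
    class_percentages = data.frame(
      shape_class = names(summary$class_percentages),
      percentage = as.vector(summary$class_percentages)
    ),
    environment_point = data.frame(mean_psi = summary$mean_psi,
                                   mean_op = summary$mean_op)
  )
}
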