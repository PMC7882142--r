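# Comparative proportional body-length estimation for incomplete skeletons.
#
# The estimator assumes isometry between the incomplete specimen and better
# known relatives: a preserved column segment (the pectoral-to-sacral "trunk")
# is extrapolated to a full post-cervical series using caudal/post-cervical
# fractions observed in complete skeletons, then to a full postcranial length
# using neck/postcranial fractions, and finally to total length by adding an
# estimated skull length. All rounding happens at reporting boundaries only.

#' Comparative proportion table entry
#'
#' One reference-taxon proportion: the length of a body part and the length of
#' the whole it is measured against. Two part kinds are understood by
#' [estimate_body_size()]:
#' \describe{
#'   \item{`caudal_of_postcervical`}{caudal series / post-cervical column
#'     (post-cervical = trunk + caudal).}
#'   \item{`neck_of_postcranial`}{cervical series / postcranial skeleton; the
#'     estimator uses the complement (1 - fraction) as the post-cervical
#'     share of the postcranium.}
#' }
#'
#' @param taxon reference taxon label.
#' @param part one of `"caudal_of_postcervical"`, `"neck_of_postcranial"`.
#' @param part_length_mm,whole_length_mm lengths in mm, `0 < part < whole`.
#' @return an object of class `comparative_proportion` (a list with the fields
#'   above plus `fraction`, the part/whole ratio to 3 decimals).
#' @examples
#' comparative_proportion("Thalassomedon", "caudal_of_postcervical", 1216, 4299)
#' @export
comparative_proportion <- function(taxon, part, part_length_mm, whole_length_mm) {
  part <- match.arg(part, c("caudal_of_postcervical", "neck_of_postcranial"))
  fr <- fraction_from_lengths(part_length_mm, whole_length_mm)
  structure(
    list(taxon = taxon, part = part, part_length_mm = part_length_mm,
         whole_length_mm = whole_length_mm, fraction = fr),
    class = "comparative_proportion"
  )
}

#' @export
print.comparative_proportion <- function(x, ...) {
  cat(sprintf("%s: %s = %.0f / %.0f mm (fraction %.3f)\n",
              x$taxon, x$part, x$part_length_mm, x$whole_length_mm, x$fraction))
  invisible(x)
}

#' Part/whole fraction from two lengths
#'
#' @param part_mm,whole_mm positive lengths with `part_mm < whole_mm`.
#' @return the fraction part/whole, rounded half-up to 3 decimals.
#' @examples
#' fraction_from_lengths(1216, 4299) # 0.283
#' fraction_from_lengths(1860, 4180) # 0.445
#' @export
fraction_from_lengths <- function(part_mm, whole_mm) {
  if (!is.finite(part_mm) || !is.finite(whole_mm) || part_mm <= 0)
    stopf("lengths must be positive finite numbers")
  if (part_mm >= whole_mm)
    stopf("part length (%g) must be smaller than whole length (%g)",
          part_mm, whole_mm)
  round_half_up(part_mm / whole_mm, 3)
}

#' Original caudal-series length from trunk length and a caudal fraction
#'
#' If the caudal series is a fraction `f` of the post-cervical column
#' (trunk + caudal), then caudal = f * trunk / (1 - f).
#'
#' @param trunk_mm pectoral-to-sacral column length, mm.
#' @param fraction caudal / post-cervical fraction, in (0, 1).
#' @return estimated caudal length in integer mm (half-up).
#' @examples
#' caudal_from_fraction(1398, 0.283) # 552
#' caudal_from_fraction(1398, 0.450) # 1144
#' @export
caudal_from_fraction <- function(trunk_mm, fraction) {
  if (trunk_mm <= 0) stopf("trunk_mm must be positive")
  if (fraction <= 0 || fraction >= 1)
    stopf("caudal fraction must lie strictly inside (0, 1), got %g", fraction)
  round_half_up(fraction * trunk_mm / (1 - fraction), 0)
}

#' Postcranial length from post-cervical length and its postcranial share
#'
#' @param postcervical_mm post-cervical column length (trunk + caudal), mm.
#' @param postcervical_fraction post-cervical / postcranial fraction in (0, 1].
#' @return postcranial length in mm (not rounded; callers report in m).
#' @examples
#' postcranial_from_postcervical(2246, 0.607) # 3700.2 mm -> 3.7 m
#' postcranial_from_postcervical(2246, 0.375) # 5989.3 mm -> 6.0 m
#' @export
postcranial_from_postcervical <- function(postcervical_mm, postcervical_fraction) {
  if (postcervical_mm <= 0) stopf("postcervical_mm must be positive")
  if (postcervical_fraction <= 0 || postcervical_fraction > 1)
    stopf("postcervical fraction must lie in (0, 1], got %g",
          postcervical_fraction)
  postcervical_mm / postcervical_fraction
}

#' Isometric linear scaling
#'
#' @param length_m length in metres.
#' @param linear_ratio dimensionless linear size ratio (> 0).
#' @return scaled length in metres, half-up to 1 decimal.
#' @examples
#' isometric_scale(5.2, 1.32) # 6.9
#' @export
isometric_scale <- function(length_m, linear_ratio) {
  if (linear_ratio <= 0) stopf("linear_ratio must be positive")
  round_half_up(length_m * linear_ratio, 1)
}

#' Specimen measurements for body-size estimation
#'
#' @param trunk_mm pectoral + dorsal + sacral column length, mm.
#' @param preserved_caudal_mm preserved (incomplete) caudal series length, mm.
#' @param skull_mm estimated skull length, mm.
#' @param scale_ratio_to_largest linear ratio of the largest referred specimen
#'   to this one (>= 1; 1 means this is the largest known individual).
#' @return an object of class `specimen_measurements`.
#' @export
specimen_measurements <- function(trunk_mm, preserved_caudal_mm, skull_mm,
                                  scale_ratio_to_largest = 1) {
  if (any(c(trunk_mm, preserved_caudal_mm, skull_mm) <= 0))
    stopf("all lengths must be positive")
  if (scale_ratio_to_largest < 1)
    stopf("scale_ratio_to_largest must be >= 1")
  structure(
    list(trunk_mm = trunk_mm, preserved_caudal_mm = preserved_caudal_mm,
         skull_mm = skull_mm, scale_ratio_to_largest = scale_ratio_to_largest),
    class = "specimen_measurements"
  )
}

#' Chained proportional body-size estimate
#'
#' Runs the full comparative chain: (1) caudal-series range from the extreme
#' caudal/post-cervical fractions in `props`; (2) caudal average = midpoint of
#' the reported range; (3) post-cervical length = trunk + caudal average;
#' (4) postcranial range from the extreme post-cervical/postcranial shares
#' (complements of the neck fractions); (5) total range = postcranial + skull,
#' reported in m to 1 decimal; (6) total average = midpoint of the reported
#' total range; (7) isometric scaling to the largest referred specimen.
#' Rounding (half-up) is applied only where a quantity is reported: caudal
#' lengths to integer mm, metre values to 1 decimal.
#'
#' @param spec a [specimen_measurements()] object.
#' @param props a list of [comparative_proportion()] objects containing at
#'   least one entry of each part kind.
#' @return an object of class `body_size_estimate`: ranges, averages, the
#'   scaled total, and a `provenance` data frame recording every step with its
#'   inputs and output.
#' @examples
#' props <- list(
#'   comparative_proportion("Thalassomedon", "caudal_of_postcervical", 1216, 4299),
#'   comparative_proportion("Morenosaurus", "caudal_of_postcervical", 1632, 3627),
#'   comparative_proportion("Nakonanectes", "neck_of_postcranial", 2083, 5300),
#'   comparative_proportion("Albertonectes", "neck_of_postcranial", 7000, 11200)
#' )
#' est <- estimate_body_size(
#'   specimen_measurements(1398, 400, 300, scale_ratio_to_largest = 1.32),
#'   props
#' )
#' est$total_avg_m    # 5.2
#' est$scaled_total_m # 6.9
#' @export
estimate_body_size <- function(spec, props) {
  stopifnot(inherits(spec, "specimen_measurements"))
  if (!length(props) || !all(vapply(props, inherits, TRUE, "comparative_proportion")))
    stopf("props must be a non-empty list of comparative_proportion objects")
  parts <- vapply(props, `[[`, "", "part")
  caud_f <- vapply(props[parts == "caudal_of_postcervical"], `[[`, 0, "fraction")
  neck_f <- vapply(props[parts == "neck_of_postcranial"], `[[`, 0, "fraction")
  if (!length(caud_f)) stopf("no caudal_of_postcervical proportion supplied")
  if (!length(neck_f)) stopf("no neck_of_postcranial proportion supplied")

  steps <- list()
  log_step <- function(label, inputs, output) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = label, inputs = inputs, output = output,
      stringsAsFactors = FALSE
    )
  }

  caud_lo <- caudal_from_fraction(spec$trunk_mm, min(caud_f))
  caud_hi <- caudal_from_fraction(spec$trunk_mm, max(caud_f))
  log_step("caudal_low_mm",
           sprintf("trunk=%g, fraction=%.3f", spec$trunk_mm, min(caud_f)),
           caud_lo)
  log_step("caudal_high_mm",
           sprintf("trunk=%g, fraction=%.3f", spec$trunk_mm, max(caud_f)),
           caud_hi)

  caud_avg <- round_half_up((caud_lo + caud_hi) / 2, 0)
  log_step("caudal_avg_mm", sprintf("midpoint of %g and %g", caud_lo, caud_hi),
           caud_avg)

  postcervical <- spec$trunk_mm + caud_avg
  log_step("postcervical_mm",
           sprintf("trunk=%g + caudal_avg=%g", spec$trunk_mm, caud_avg),
           postcervical)

  pc_shares <- 1 - neck_f  # post-cervical share of the postcranium
  post_lo <- postcranial_from_postcervical(postcervical, max(pc_shares))
  post_hi <- postcranial_from_postcervical(postcervical, min(pc_shares))
  post_lo_m <- round_half_up(post_lo / 1000, 1)
  post_hi_m <- round_half_up(post_hi / 1000, 1)
  log_step("postcranial_low_m",
           sprintf("postcervical=%g / share=%.3f", postcervical, max(pc_shares)),
           post_lo_m)
  log_step("postcranial_high_m",
           sprintf("postcervical=%g / share=%.3f", postcervical, min(pc_shares)),
           post_hi_m)

  tot_lo_m <- round_half_up((post_lo + spec$skull_mm) / 1000, 1)
  tot_hi_m <- round_half_up((post_hi + spec$skull_mm) / 1000, 1)
  log_step("total_low_m",
           sprintf("postcranial=%g mm + skull=%g mm", post_lo, spec$skull_mm),
           tot_lo_m)
  log_step("total_high_m",
           sprintf("postcranial=%g mm + skull=%g mm", post_hi, spec$skull_mm),
           tot_hi_m)

  tot_avg_m <- round_half_up((tot_lo_m + tot_hi_m) / 2, 1)
  log_step("total_avg_m",
           sprintf("midpoint of %.1f and %.1f", tot_lo_m, tot_hi_m), tot_avg_m)

  scaled_m <- isometric_scale(tot_avg_m, spec$scale_ratio_to_largest)
  log_step("scaled_total_m",
           sprintf("total_avg=%.1f * ratio=%g", tot_avg_m,
                   spec$scale_ratio_to_largest),
           scaled_m)

  structure(
    list(
      caudal_range_mm = c(low = caud_lo, high = caud_hi),
      caudal_avg_mm = caud_avg,
      postcervical_mm = postcervical,
      postcranial_range_m = c(low = post_lo_m, high = post_hi_m),
      total_range_m = c(low = tot_lo_m, high = tot_hi_m),
      total_avg_m = tot_avg_m,
      scaled_total_m = scaled_m,
      provenance = do.call(rbind, steps)
    ),
    class = "body_size_estimate"
  )
}

#' @export
print.body_size_estimate <- function(x, ...) {
  cat("Proportional body-size estimate\n")
  cat(sprintf("  caudal series:  %.0f-%.0f mm (avg %.0f mm)\n",
              x$caudal_range_mm[["low"]], x$caudal_range_mm[["high"]],
              x$caudal_avg_mm))
  cat(sprintf("  post-cervical:  %g mm\n", x$postcervical_mm))
  cat(sprintf("  postcranial:    %.1f-%.1f m\n",
              x$postcranial_range_m[["low"]], x$postcranial_range_m[["high"]]))
  cat(sprintf("  total length:   %.1f-%.1f m (avg %.1f m)\n",
              x$total_range_m[["low"]], x$total_range_m[["high"]],
              x$total_avg_m))
  cat(sprintf("  largest specimen (isometric): %.1f m\n", x$scaled_total_m))
  invisible(x)
}

#' Reference comparative-proportion table
#'
#' The comparative proportions used for elasmosaurid body-length estimation:
#' caudal/post-cervical fractions for *Thalassomedon* (1,216/4,299 mm),
#' *Albertonectes* (1,860/4,180 mm) and *Morenosaurus* (1,632/3,627 mm), and
#' neck/postcranial fractions for *Nakonanectes* (2.2/5.3 m, the shortest
#' proportional neck) and *Albertonectes* (7.0/11.2 m, the longest).
#'
#' @param as_data_frame return a data frame instead of a list of
#'   [comparative_proportion()] objects.
#' @return list of `comparative_proportion` objects (or a data frame).
#' @export
reference_proportions <- function(as_data_frame = FALSE) {
  df <- data.frame(
    taxon = c("Thalassomedon", "Albertonectes", "Morenosaurus",
              "Nakonanectes", "Albertonectes"),
    part = c(rep("caudal_of_postcervical", 3), rep("neck_of_postcranial", 2)),
    part_length_mm = c(1216, 1860, 1632, 2083, 7000),
    whole_length_mm = c(4299, 4180, 3627, 5300, 11200),
    stringsAsFactors = FALSE
  )
  if (as_data_frame) return(df)
  lapply(seq_len(nrow(df)), function(i)
    comparative_proportion(df$taxon[i], df$part[i],
                           df$part_length_mm[i], df$whole_length_mm[i]))
}
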