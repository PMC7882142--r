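# End-to-end orchestration: run any subset of the four analyses from one
# configuration, writing per-stage machine-readable reports and artifacts
# plus a top-level run report recording versions, seeds and input digests.

#' Run the analysis pipeline
#'
#' Executes the enabled stages in the fixed order bodysize, gastroliths,
#' orientations, parsimony. Each stage writes `<stage>_report.json` (and its
#' artifacts: consensus Newick trees, summary CSVs) under `out_dir`; a
#' top-level `run_report.json` concatenates the stage summaries with package
#' version, seed and MD5 digests of every input file. A stage failure halts
#' the run with an error after the partial top-level report has been written.
#'
#' @param config a list with `out_dir`, optional `seed` (default 20210211),
#'   and a `stages` list holding any subset of:
#' \describe{
#'   \item{`bodysize`}{`proportions_csv`, `trunk_mm`, `preserved_caudal_mm`,
#'     `skull_mm`, `scale_ratio_to_largest`.}
#'   \item{`gastroliths`}{`clast_csv`, optional `mass_bin_width_g`, `scheme`.}
#'   \item{`orientations`}{`angle_csv`, optional `axial`, `n_sims`,
#'     `rose_bin_width_deg`.}
#'   \item{`parsimony`}{`nexus`, optional `n_replicates`,
#'     `trees_kept_per_replicate`, `max_trees_total`, `n_boot`, `outgroup`,
#'     `max_wildcards`.}
#' }
#' @param verbose integer 0-2; progress notes go to standard error, never
#'   numerical results.
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(config, verbose = 1) {
  if (is.null(config$out_dir)) stopf("config$out_dir is required")
  stages <- config$stages
  known <- c("bodysize", "gastroliths", "orientations", "parsimony")
  stages <- stages[intersect(known, names(stages))]
  if (!length(stages)) stopf("no stages enabled")
  seed <- config$seed %||% 20210211

  paths <- unlist(lapply(stages, function(s)
    s[grepl("_csv$|^nexus$", names(s))]), use.names = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stopf("input not found: %s", missing[1])

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(lvl, ...) if (verbose >= lvl) message(...)

  report <- list(
    package = "quarrypal",
    version = as.character(utils::packageVersion("quarrypal")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    inputs = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = list()
  )
  write_report <- function(x, name) {
    jsonlite::write_json(x, file.path(config$out_dir, name),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  run_stage <- function(name, fun) {
    say(1, "stage: ", name)
    res <- tryCatch(fun(), error = function(e) {
      report$stages[[name]] <<- list(status = "error",
                                     message = conditionMessage(e))
      write_report(report, "run_report.json")
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    report$stages[[name]] <<- c(list(status = "ok"), res)
    write_report(res, paste0(name, "_report.json"))
  }

  if (!is.null(stages$bodysize)) run_stage("bodysize", function() {
    s <- stages$bodysize
    df <- utils::read.csv(s$proportions_csv, stringsAsFactors = FALSE)
    props <- lapply(seq_len(nrow(df)), function(i)
      comparative_proportion(df$taxon[i], df$part[i],
                             df$part_length_mm[i], df$whole_length_mm[i]))
    est <- estimate_body_size(
      specimen_measurements(s$trunk_mm, s$preserved_caudal_mm, s$skull_mm,
                            s$scale_ratio_to_largest %||% 1),
      props)
    list(
      caudal_range_mm = as.list(est$caudal_range_mm),
      caudal_avg_mm = est$caudal_avg_mm,
      postcervical_mm = est$postcervical_mm,
      postcranial_range_m = as.list(est$postcranial_range_m),
      total_range_m = as.list(est$total_range_m),
      total_avg_m = est$total_avg_m,
      scaled_total_m = est$scaled_total_m,
      provenance = est$provenance
    )
  })

  if (!is.null(stages$gastroliths)) run_stage("gastroliths", function() {
    s <- stages$gastroliths
    clasts <- read_clast_table(s$clast_csv)
    smry <- summarize_clasts(clasts,
                             mass_bin_width_g = s$mass_bin_width_g %||% 2,
                             scheme = s$scheme %||% "zingg")
    pd <- clast_plot_data(smry)
    for (nm in names(pd))
      utils::write.csv(pd[[nm]],
                       file.path(config$out_dir,
                                 paste0("gastroliths_", nm, ".csv")),
                       row.names = FALSE)
    list(n = smry$n, scheme = smry$scheme,
         mean_psi = smry$mean_psi, sd_psi = smry$sd_psi,
         mean_op = smry$mean_op, sd_op = smry$sd_op,
         n_op_excluded = smry$n_op_excluded,
         class_percentages = as.list(smry$class_percentages),
         mass = smry$mass[c("n", "min", "max", "mean", "total")])
  })

  if (!is.null(stages$orientations)) run_stage("orientations", function() {
    s <- stages$orientations
    sample <- read_angle_table(s$angle_csv, axial = s$axial %||% TRUE)
    bat <- orientation_battery(sample, n_sims = s$n_sims %||% 10000,
                               seed = seed)
    utils::write.csv(rose_bins(sample, s$rose_bin_width_deg %||% 10),
                     file.path(config$out_dir, "orientations_rose.csv"),
                     row.names = FALSE)
    tst <- function(t) list(statistic = as.list(t$statistic),
                            p_value = t$p_value,
                            p_range = t$p_range, method = t$method,
                            n_sims = t$n_sims, seed = t$seed)
    list(n = sample$n, axial = sample$axial,
         mean_axis_deg = bat$summary$mean_axis_deg,
         R = bat$summary$R, circ_variance = bat$summary$circ_variance,
         ci95_deg = bat$summary$ci95_deg, ci_valid = bat$summary$ci_valid,
         rayleigh = tst(bat$rayleigh), rao = tst(bat$rao),
         watson = tst(bat$watson), kuiper = tst(bat$kuiper))
  })

  if (!is.null(stages$parsimony)) run_stage("parsimony", function() {
    s <- stages$parsimony
    cm <- read_nexus(s$nexus)
    cfg <- search_config(
      n_replicates = s$n_replicates %||% 10,
      trees_kept_per_replicate = s$trees_kept_per_replicate %||% 10,
      seed = seed,
      max_trees_total = s$max_trees_total %||% 1000)
    ts <- heuristic_search(cm, cfg)
    strict <- strict_consensus(ts)
    write_newick(strict, file.path(config$out_dir, "strict_consensus.nwk"))
    ci_ri <- ensemble_ci_ri(ts$length, cm)
    wc <- if (ts$n_trees >= 2)
      find_wildcards(ts$trees, max_wildcards = s$max_wildcards %||% 5,
                     outgroup = s$outgroup)
    else list(wildcards = character(0))
    out <- list(n_taxa = cm$n_taxa, n_chars = cm$n_chars,
                best_length = ts$length, n_mpts = ts$n_trees,
                CI = ci_ri$CI, RI = ci_ri$RI,
                wildcards = wc$wildcards,
                search = ts$metadata)
    if (length(wc$wildcards)) {
      red <- reduced_consensus(ts$trees, wc$wildcards, matrix = cm)
      write_newick(red$consensus,
                   file.path(config$out_dir, "reduced_strict_consensus.nwk"))
      out$reduced <- list(n_trees = red$n_trees,
                          lengths = sort(unique(red$lengths)))
    }
    if (!is.null(s$n_boot) && s$n_boot > 0) {
      bs <- bootstrap_support(cm, cfg, n_boot = s$n_boot)
      write_newick(annotate_support(strict, bs),
                   file.path(config$out_dir,
                             "strict_consensus_bootstrap.nwk"))
      out$bootstrap <- list(n_boot = bs$n_boot,
                            support = as.list(bs$support))
    }
    out
  })

  write_report(report, "run_report.json")
  say(1, "pipeline complete: ", config$out_dir)
  invisible(report)
}
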