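#' Reference division policy
#'
#' Asymmetric antigen division (P = 0.72, L = 1.0) with always-symmetric TF
#' division: the regime previously shown to reproduce experimental DZ-to-LZ
#' ratios, used as the default when a run configuration gives no policy.
#'
#' @return A \code{\link{division_policy}}.
#' @export
reference_policy <- function() {
  division_policy(p_ag = 0.72, p_tf = 0, l_ag = 1.0, coupling = "ag_only")
}

known_keys <- list(
  top = c("seed", "policy", "engine"),
  policy = c("p_ag", "p_tf", "l_ag", "l_blimp1", "l_bcl6", "l_irf4",
             "coupling"),
  engine = c("duration", "dt", "sample_cadence", "n_founders",
             "founder_window", "founder_divisions", "cb_cycle",
             "cycle_jitter", "recycle_divisions", "cb_to_cc_delay",
             "cc_lifetime", "await_lifetime", "collect_window",
             "fdc_test_rate", "tfh_window",
             "tfh_help_needed", "p_mut", "founder_dist", "grn", "shape",
             "resources", "thresholds"),
  grn = c("mu_p", "mu_b", "mu_r", "sigma_p", "sigma_b", "sigma_r",
          "k_p", "k_b", "k_r", "lambda_p", "lambda_b", "lambda_r",
          "bcr0", "cd0"),
  shape = c("dimension", "gamma"),
  resources = c("n_fdc_sites", "n_tfh"),
  thresholds = c("blimp1_pc_threshold", "irf4_critical"))

check_keys <- function(lst, block) {
  bad <- setdiff(names(lst), known_keys[[block]])
  if (length(bad))
    stop("unknown key(s) in ", if (block == "top") "configuration" else block,
         " block: ", paste(bad, collapse = ", "))
  invisible(lst)
}

#' Build a run configuration from a plain list
#'
#' Applies defaults for absent keys and validates every value through the
#' component constructors. The same schema is used by configuration files and
#' by the configuration echo in \code{summary.json}, so an echoed
#' configuration reproduces its run exactly.
#'
#' @param lst Nested list (see \code{\link{load_config}} for the schema).
#' @return List of class \code{run_config} with elements \code{engine},
#'   \code{policy}, \code{seed}.
#' @export
config_from_list <- function(lst) {
  if (is.null(lst)) lst <- list()
  check_keys(lst, "top")
  pol <- if (is.null(lst$policy)) reference_policy() else {
    check_keys(lst$policy, "policy")
    do.call(division_policy, lst$policy)
  }
  ecfg <- if (is.null(lst$engine)) list() else lst$engine
  check_keys(ecfg, "engine")
  sub <- function(block, ctor) {
    if (is.null(ecfg[[block]])) ctor()
    else { check_keys(ecfg[[block]], block); do.call(ctor, ecfg[[block]]) }
  }
  grn <- sub("grn", grn_parameters)
  shape <- sub("shape", affinity_model)
  res <- sub("resources", lz_resources)
  thrs <- sub("thresholds", fate_thresholds)
  ecfg[c("grn", "shape", "resources", "thresholds")] <- NULL
  if (!is.null(ecfg$founder_dist)) ecfg$founder_dist <-
      as.numeric(unlist(ecfg$founder_dist))
  engine <- do.call(engine_config,
                    c(ecfg, list(grn = grn, shape = shape, resources = res,
                                 thresholds = thrs,
                                 seed = if (is.null(lst$seed)) 1L
                                 else as.integer(lst$seed))))
  structure(list(engine = engine, policy = pol, seed = engine$seed),
            class = "run_config")
}

#' Load a run configuration file
#'
#' Reads a YAML configuration with up to three top-level blocks:
#' \code{seed} (integer), \code{policy} (fields of
#' \code{\link{division_policy}}) and \code{engine} (fields of
#' \code{\link{engine_config}}, with nested \code{grn}, \code{shape},
#' \code{resources} and \code{thresholds} blocks). Absent keys take package
#' defaults (the default policy is the reference asymmetric-antigen policy);
#' unknown keys and out-of-range values are rejected with an error naming the
#' key.
#'
#' @param path Path to the YAML file.
#' @return A \code{run_config} list (\code{engine}, \code{policy},
#'   \code{seed}).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  config_from_list(yaml::read_yaml(path))
}

#' Echo a configuration as a plain list
#'
#' Inverse of \code{\link{config_from_list}}: a nested plain list in the
#' configuration-file schema, sufficient to reproduce the run.
#'
#' @param engine \code{\link{engine_config}}.
#' @param policy \code{\link{division_policy}}.
#' @param seed Seed used for the run.
#' @return Nested list.
#' @export
config_echo <- function(engine, policy, seed) {
  e <- unclass(engine)
  list(seed = as.integer(seed),
       policy = unclass(policy),
       engine = c(e[setdiff(known_keys$engine,
                            c("grn", "shape", "resources", "thresholds"))],
                  list(grn = unclass(e$grn),
                       shape = unclass(e$shape)[c("dimension", "gamma")],
                       resources = unclass(e$resources),
                       thresholds = unclass(e$thresholds))))
}

#' Write the standard output files of a run
#'
#' Writes \code{timeseries.csv}, \code{output_cells.csv},
#' \code{summary.json} (totals, switch metrics, configuration echo, seed) and
#' \code{manifest.json} (package version, seed, wall-clock times, file
#' inventory with MD5 checksums) into \code{directory}.
#'
#' @param record A \code{\link{gc_run}}.
#' @param directory Output directory (created if missing).
#' @param quiet Suppress the progress message.
#' @return Invisibly, the manifest list.
#' @export
write_outputs <- function(record, directory, quiet = TRUE) {
  stopifnot(inherits(record, "gc_run"))
  t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  ts_path <- file.path(directory, "timeseries.csv")
  oc_path <- file.path(directory, "output_cells.csv")
  sm_path <- file.path(directory, "summary.json")
  ok <- tryCatch({
    utils::write.csv(record$timeseries, ts_path, row.names = FALSE)
    oc <- record$output_cells
    oc_out <- data.frame(exit_time_h = oc$exit_time_h,
                         type = c("PC", "MBC")[oc$type],
                         ag_status = oc$ag_status == 1,
                         blimp1 = oc$blimp1)
    utils::write.csv(oc_out, oc_path, row.names = FALSE)
    TRUE
  }, error = function(e)
    stop("failed writing run outputs under ", directory, ": ",
         conditionMessage(e)))
  sw <- switch_metrics(record)
  summary <- list(
    totals = list(pc = record$counters$pc, mbc = record$counters$mbc,
                  oc = record$counters$pc + record$counters$mbc,
                  cells_created = record$counters$created,
                  apoptosed = record$counters$apoptosed),
    switch = sw[c("frac_pc_before", "frac_pc_after", "switch_flag",
                  "defined")],
    mbc_production_span = sw$mbc_production_span,
    config = config_echo(record$config, record$policy, record$seed))
  jsonlite::write_json(summary, sm_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  files <- c(ts_path, oc_path, sm_path)
  manifest <- list(
    package = "gcasym",
    version = as.character(utils::packageVersion("gcasym")),
    seed = record$seed,
    started = t0, finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!quiet)
    message("wrote ", length(files) + 1L, " files to ", directory)
  invisible(manifest)
}

#' Re-run a simulation from a written summary.json
#'
#' Reads the configuration echo and seed from a run directory and repeats the
#' simulation; with unchanged software this reproduces the outputs exactly.
#'
#' @param directory A directory written by \code{\link{write_outputs}}.
#' @return A \code{\link{gc_run}}.
#' @export
rerun_from_summary <- function(directory) {
  s <- jsonlite::read_json(file.path(directory, "summary.json"),
                           simplifyVector = TRUE)
  cfg <- config_from_list(s$config)
  gc_run(cfg$engine, cfg$policy, seed = cfg$seed)
}
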