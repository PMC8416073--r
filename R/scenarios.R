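#' Scenario configuration
#'
#' Bundles a division policy with engine settings and a seed list into one
#' runnable simulation scenario.
#'
#' @param set_id Scenario-set identifier (1 = cosegregating TFs, 2 =
#'   per-factor polarity levels).
#' @param sim_number Simulation number within the set.
#' @param policy \code{\link{division_policy}}.
#' @param engine \code{\link{engine_config}}.
#' @param seeds Integer vector of seeds for repeated runs.
#' @param label Human-readable description.
#' @return An object of class \code{scenario_config}.
#' @export
scenario_config <- function(set_id, sim_number, policy,
                            engine = engine_config(), seeds = engine$seed,
                            label = "") {
  stopifnot(inherits(policy, "division_policy"),
            inherits(engine, "engine_config"))
  structure(list(set_id = as.integer(set_id),
                 sim_number = as.integer(sim_number),
                 policy = policy, engine = engine,
                 seeds = as.integer(seeds), label = label),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> set %d, simulation %d: %s\n",
              x$set_id, x$sim_number, x$label))
  print(x$policy)
  invisible(x)
}

#' The nine cosegregating-TF scenarios (set 1)
#'
#' Transcription factors cosegregate with one common polarity level L_TF.
#' Simulations 1-3 cover fully symmetric division, TF-only asymmetry and the
#' reference (antigen-only asymmetry); 4-6 couple TF asymmetry to antigen
#' asymmetry (one Bernoulli draw, P = 0.72) with L_TF 1.0/0.9/0.75; 7-9 make
#' TF division always asymmetric (P_TF = 1) independent of the antigen draw
#' (P_Ag = 0.72). Whenever antigen divides asymmetrically, L_Ag = 1.
#'
#' @param engine \code{\link{engine_config}} shared by all scenarios.
#' @param seeds Seed vector attached to every scenario.
#' @return List of nine \code{\link{scenario_config}} objects.
#' @export
build_set1 <- function(engine = engine_config(), seeds = engine$seed) {
  mk <- function(sim, policy, label)
    scenario_config(1L, sim, policy, engine, seeds, label)
  tfpol <- function(p_tf, l, p_ag, l_ag, coupling)
    division_policy(p_ag = p_ag, p_tf = p_tf, l_ag = l_ag,
                    l_blimp1 = l, l_bcl6 = l, l_irf4 = l,
                    coupling = coupling)
  list(
    mk(1L, division_policy(coupling = "none"),
       "(i) symmetric Ag and TF division (P_Ag = P_TF = 0)"),
    mk(2L, tfpol(0.72, 1.0, 0, 0.5, "tf_only"),
       "(ii) symmetric Ag, asymmetric TF division (P_TF = 0.72, L_TF = 1.0)"),
    mk(3L, tfpol(0, 0.5, 0.72, 1.0, "ag_only"),
       "(iii) symmetric TF, asymmetric Ag division (reference)"),
    mk(4L, tfpol(0.72, 1.0, 0.72, 1.0, "coupled"),
       "(iv) coupled asymmetric division, L_TF = 1.0"),
    mk(5L, tfpol(0.72, 0.9, 0.72, 1.0, "coupled"),
       "(iv) coupled asymmetric division, L_TF = 0.9"),
    mk(6L, tfpol(0.72, 0.75, 0.72, 1.0, "coupled"),
       "(iv) coupled asymmetric division, L_TF = 0.75"),
    mk(7L, tfpol(1.0, 1.0, 0.72, 1.0, "uncoupled"),
       "(v) uncoupled: always asymmetric TF division, L_TF = 1.0"),
    mk(8L, tfpol(1.0, 0.9, 0.72, 1.0, "uncoupled"),
       "(v) uncoupled: always asymmetric TF division, L_TF = 0.9"),
    mk(9L, tfpol(1.0, 0.75, 0.72, 1.0, "uncoupled"),
       "(v) uncoupled: always asymmetric TF division, L_TF = 0.75"))
}

#' The 27 per-factor polarity scenarios (set 2)
#'
#' Coupled asymmetric division (P_Ag = P_TF = 0.72, L_Ag = 1.0) with the full
#' factorial of per-factor polarity levels L_BLIMP1 x L_IRF4 x L_BCL6 over
#' \{1.0, 0.9, 0.75\}, ordered with IRF4 as the outer, BCL6 as the middle and
#' BLIMP1 as the inner (fastest-changing) level.
#'
#' @inheritParams build_set1
#' @return List of 27 \code{\link{scenario_config}} objects.
#' @export
build_set2 <- function(engine = engine_config(), seeds = engine$seed) {
  lv <- c(1.0, 0.9, 0.75)
  out <- vector("list", 27L)
  sim <- 0L
  for (l_irf4 in lv) for (l_bcl6 in lv) for (l_blimp1 in lv) {
    sim <- sim + 1L
    pol <- division_policy(p_ag = 0.72, p_tf = 0.72, l_ag = 1.0,
                           l_blimp1 = l_blimp1, l_bcl6 = l_bcl6,
                           l_irf4 = l_irf4, coupling = "coupled")
    out[[sim]] <- scenario_config(
      2L, sim, pol, engine, seeds,
      sprintf("coupled, L_BLIMP1 = %g, L_IRF4 = %g, L_BCL6 = %g",
              l_blimp1, l_irf4, l_bcl6))
  }
  out
}

#' Scenario tables as data frames
#'
#' Flat canonical representation of the scenario sets, used for the golden
#' fixture comparison and CSV export.
#'
#' @param set Which set (1 or 2).
#' @return Data frame with one row per simulation.
#' @export
scenario_table <- function(set = 1) {
  scn <- if (set == 1) build_set1() else build_set2()
  do.call(rbind, lapply(scn, function(s) {
    data.frame(set_id = s$set_id, sim = s$sim_number,
               coupling = s$policy$coupling,
               p_ag = s$policy$p_ag, p_tf = s$policy$p_tf,
               l_ag = s$policy$l_ag, l_blimp1 = s$policy$l_blimp1,
               l_bcl6 = s$policy$l_bcl6, l_irf4 = s$policy$l_irf4)
  }))
}

#' Repeat a scenario over several seeds
#'
#' Runs a scenario once per seed and summarizes per-time-point dispersion
#' (median and interquartile band) of the main observables.
#'
#' @param scenario \code{\link{scenario_config}}.
#' @param n_seeds Number of seeds; defaults to the scenario's seed list, and
#'   when larger, extends it consecutively from the first seed.
#' @return List with \code{records} (one \code{\link{gc_run}} per seed) and
#'   \code{summary} (data frame: per time point, median and quartiles of CB
#'   count, live CC count, cumulative PC/MBC and DZ-to-LZ ratio).
#' @export
run_with_repeats <- function(scenario, n_seeds = length(scenario$seeds)) {
  stopifnot(inherits(scenario, "scenario_config"), n_seeds >= 1)
  seeds <- if (n_seeds <= length(scenario$seeds))
    scenario$seeds[seq_len(n_seeds)]
  else scenario$seeds[1L] + seq_len(n_seeds) - 1L
  records <- lapply(seeds, function(s)
    gc_run(scenario$engine, scenario$policy, seed = s))
  qs <- function(m) apply(m, 1, stats::quantile,
                          probs = c(0.25, 0.5, 0.75), names = FALSE)
  pull <- function(col) sapply(records, function(r) r$timeseries[[col]])
  tm <- records[[1L]]$timeseries$time_h
  out <- data.frame(time_h = tm)
  for (col in c("cb", "cc_live", "pc_cum", "mbc_cum", "dz_lz_ratio")) {
    q <- qs(pull(col))
    out[[paste0(col, "_q1")]] <- q[1, ]
    out[[paste0(col, "_med")]] <- q[2, ]
    out[[paste0(col, "_q3")]] <- q[3, ]
  }
  list(records = records, summary = out, seeds = seeds)
}
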