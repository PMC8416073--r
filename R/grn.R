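#' Transcription-factor state of a germinal-center B cell
#'
#' Concentrations of the three core regulators of plasma-cell differentiation,
#' in model units of 1e-8 M. The founder centroblast state is
#' \code{tf_state(0, 5, 0)}; the plasmablast reference state used in the
#' daughter-cell experiments is \code{tf_state(8, 2, 2)}.
#'
#' @param blimp1,bcl6,irf4 Non-negative finite concentrations (model units).
#' @return A named numeric vector of class \code{tf_state}.
#' @export
#' @examples
#' founder <- tf_state(0, 5, 0)
tf_state <- function(blimp1, bcl6, irf4) {
  s <- c(blimp1 = as.numeric(blimp1), bcl6 = as.numeric(bcl6),
         irf4 = as.numeric(irf4))
  validate_tf_state(s)
  structure(s, class = "tf_state")
}

validate_tf_state <- function(s) {
  if (length(s) != 3L || !is.numeric(s))
    stop("a TF state is three numeric concentrations (blimp1, bcl6, irf4)")
  if (any(!is.finite(s)) || any(s < 0))
    stop("TF concentrations must be finite and >= 0; got (",
         paste(signif(unclass(s), 4), collapse = ", "), ")")
  invisible(s)
}

#' Parameters of the BLIMP1/BCL6/IRF4 regulatory network
#'
#' Kinetic constants of the bistable three-factor network: basal production
#' rates \code{mu_*}, maximal induced production \code{sigma_*}, dissociation
#' constants \code{k_*} (Hill coefficient 2), first-order degradation rates
#' \code{lambda_*}, and the scales of the two upstream signals: \code{bcr0}
#' multiplies the BcR signal (extra BCL6 degradation while a centrocyte is in
#' contact with FDC-held antigen) and \code{cd0} multiplies the
#' affinity-weighted CD40 signal (extra IRF4 production during Tfh help).
#' Concentration unit is 1e-8 M, time unit hours.
#'
#' Under the defaults and zero signals the network has exactly two stable
#' states: BCL6-high (centroblast/centrocyte/memory phenotype) and
#' BLIMP1/IRF4-high (plasma-cell phenotype).
#'
#' @param mu_p,mu_b,mu_r Basal production rates (units/h).
#' @param sigma_p,sigma_b,sigma_r Maximal induced production rates (units/h).
#' @param k_p,k_b,k_r Dissociation constants (units).
#' @param lambda_p,lambda_b,lambda_r Degradation rates (1/h).
#' @param bcr0,cd0 Signal scales (1/h-equivalent).
#' @return An object of class \code{grn_params}.
#' @export
grn_parameters <- function(mu_p = 1e-6, mu_b = 2, mu_r = 0.1,
                           sigma_p = 9, sigma_b = 100, sigma_r = 2.6,
                           k_p = 1, k_b = 1, k_r = 1,
                           lambda_p = 1, lambda_b = 1, lambda_r = 1,
                           bcr0 = 16, cd0 = 7.5) {
  q <- c(mu_p = mu_p, mu_b = mu_b, mu_r = mu_r,
         sigma_p = sigma_p, sigma_b = sigma_b, sigma_r = sigma_r,
         k_p = k_p, k_b = k_b, k_r = k_r,
         lambda_p = lambda_p, lambda_b = lambda_b, lambda_r = lambda_r,
         bcr0 = bcr0, cd0 = cd0)
  if (any(!is.finite(q)) || any(q[1:12] <= 0) || any(q[13:14] < 0))
    stop("GRN kinetic parameters must be strictly positive ",
         "(signal scales may be zero)")
  structure(as.list(q), class = "grn_params")
}

#' @export
print.grn_params <- function(x, ...) {
  cat("<grn_params> BLIMP1/BCL6/IRF4 network (units 1e-8 M, hours)\n")
  v <- unlist(x)
  cat(paste(sprintf("  %-8s %g", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

param_vec <- function(params) {
  stopifnot(inherits(params, "grn_params"))
  as.numeric(unlist(params))
}

#' Upstream signal input to the network
#'
#' @param bcr_on Logical; BcR signalling active (antigen collection contact).
#' @param cd40_affinity Affinity in \code{[0, 1]} scaling the CD40 signal
#'   (0 = no Tfh contact).
#' @return An object of class \code{signal_input}.
#' @export
signal_input <- function(bcr_on = FALSE, cd40_affinity = 0) {
  if (!is.numeric(cd40_affinity) || cd40_affinity < 0 || cd40_affinity > 1)
    stop("cd40_affinity must lie in [0, 1]")
  structure(list(bcr_on = isTRUE(bcr_on) || identical(bcr_on, 1),
                 cd40_affinity = as.numeric(cd40_affinity)),
            class = "signal_input")
}

#' Thresholds used to classify differentiation states
#'
#' @param blimp1_pc_threshold BLIMP1 level (model units) at or above which a
#'   cell is BLIMP1-high, i.e. committed to the plasma-cell program (default 8,
#'   corresponding to 8e-8 M).
#' @param irf4_critical Diagnostic IRF4 level (default 1) above which the
#'   IRF4-positive feedback is self-sustaining.
#' @return An object of class \code{fate_thresholds}.
#' @export
fate_thresholds <- function(blimp1_pc_threshold = 8, irf4_critical = 1) {
  if (blimp1_pc_threshold <= 0 || irf4_critical <= 0)
    stop("thresholds must be > 0")
  structure(list(blimp1_pc_threshold = blimp1_pc_threshold,
                 irf4_critical = irf4_critical),
            class = "fate_thresholds")
}

#' Right-hand side of the regulatory network
#'
#' Instantaneous rates of change (units/h) of BLIMP1, BCL6 and IRF4. BLIMP1 is
#' repressed by BCL6 and activated by IRF4; BCL6 is repressed by all three
#' factors; IRF4 activates itself. BcR signalling degrades BCL6 and CD40
#' signalling induces IRF4, both gated by the current BCL6 level.
#'
#' @param state TF state (numeric length 3 or \code{\link{tf_state}}).
#' @param params \code{\link{grn_parameters}}.
#' @param signals \code{\link{signal_input}}.
#' @return Named numeric rate triple (d_blimp1, d_bcl6, d_irf4).
#' @export
grn_rhs <- function(state, params = grn_parameters(),
                    signals = signal_input()) {
  validate_tf_state(state)
  p <- state[[1]]; b <- state[[2]]; r <- state[[3]]
  q <- params
  hb <- q$k_b^2 / (q$k_b^2 + b^2)
  hp <- q$k_p^2 / (q$k_p^2 + p^2)
  hr <- q$k_r^2 / (q$k_r^2 + r^2)
  hr_act <- r^2 / (q$k_r^2 + r^2)
  bcr <- q$bcr0 * as.numeric(signals$bcr_on) * hb
  cd40 <- q$cd0 * signals$cd40_affinity * hb
  c(d_blimp1 = q$mu_p + q$sigma_p * hb + q$sigma_p * hr_act - q$lambda_p * p,
    d_bcl6 = q$mu_b + q$sigma_b * hp * hb * hr - (q$lambda_b + bcr) * b,
    d_irf4 = q$mu_r + q$sigma_r * hr_act + cd40 - q$lambda_r * r)
}

grn_jacobian <- function(state, params, signals = signal_input()) {
  p <- state[[1]]; b <- state[[2]]; r <- state[[3]]
  q <- params
  hb <- q$k_b^2 / (q$k_b^2 + b^2)
  hp <- q$k_p^2 / (q$k_p^2 + p^2)
  hr <- q$k_r^2 / (q$k_r^2 + r^2)
  hr_act <- r^2 / (q$k_r^2 + r^2)
  # d/dx of k^2/(k^2+x^2) = -2 k^2 x/(k^2+x^2)^2
  dhb <- -2 * q$k_b^2 * b / (q$k_b^2 + b^2)^2
  dhp <- -2 * q$k_p^2 * p / (q$k_p^2 + p^2)^2
  dhr <- -2 * q$k_r^2 * r / (q$k_r^2 + r^2)^2
  dhr_act <- 2 * q$k_r^2 * r / (q$k_r^2 + r^2)^2
  bcr_on <- as.numeric(signals$bcr_on)
  a <- signals$cd40_affinity
  J <- matrix(0, 3, 3)
  J[1, 1] <- -q$lambda_p
  J[1, 2] <- q$sigma_p * dhb
  J[1, 3] <- q$sigma_p * dhr_act
  J[2, 1] <- q$sigma_b * dhp * hb * hr
  J[2, 2] <- q$sigma_b * hp * dhb * hr - (q$lambda_b + q$bcr0 * bcr_on * hb) -
    q$bcr0 * bcr_on * dhb * b
  J[2, 3] <- q$sigma_b * hp * hb * dhr
  J[3, 1] <- 0
  J[3, 2] <- q$cd0 * a * dhb
  J[3, 3] <- q$sigma_r * dhr_act - q$lambda_r
  J
}

#' Integrate the network with a fixed-step order-4 scheme
#'
#' @inheritParams grn_rhs
#' @param dt Step length (h), default 0.05.
#' @param duration Total time (h); the trajectory has
#'   \code{duration/dt + 1} rows.
#' @return Data frame with columns \code{time_h}, \code{blimp1}, \code{bcl6},
#'   \code{irf4}.
#' @export
#' @examples
#' tr <- grn_integrate(tf_state(0, 5, 0), duration = 10)
#' tail(tr, 1)  # settles near the BCL6-high founder attractor
grn_integrate <- function(state, params = grn_parameters(),
                          signals = signal_input(), dt = 0.05, duration) {
  validate_tf_state(state)
  if (dt <= 0) stop("dt must be > 0")
  if (duration < 0) stop("duration must be >= 0")
  n <- as.integer(round(duration / dt))
  if (duration > 0 && n < 1L)
    stop("duration must be at least dt")
  m <- grn_traj_cpp(as.numeric(state), param_vec(params),
                    as.numeric(signals$bcr_on), signals$cd40_affinity, dt, n)
  data.frame(time_h = seq(0, by = dt, length.out = n + 1L),
             blimp1 = m[, 1], bcl6 = m[, 2], irf4 = m[, 3])
}

#' Locate the fixed points of the autonomous network
#'
#' Deterministic multi-start search: Newton root-polishing from every
#' combination of \{0, 0.5, 1, 2, 5, 10\} per factor, followed by
#' de-duplication and stability classification via the eigenvalues of the
#' analytic Jacobian. Signals are fixed at zero.
#'
#' @param params \code{\link{grn_parameters}}.
#' @param tol Newton convergence tolerance on the max-norm of the rates.
#' @return Data frame with columns \code{blimp1}, \code{bcl6}, \code{irf4},
#'   \code{stable} (logical) and \code{residual}, ordered by increasing BLIMP1.
#'   Empty (with a warning) if no start converges.
#' @export
grn_steady_states <- function(params = grn_parameters(), tol = 1e-12) {
  sig0 <- signal_input()
  grid <- c(0, 0.5, 1, 2, 5, 10)
  starts <- as.matrix(expand.grid(blimp1 = grid, bcl6 = grid, irf4 = grid,
                                  KEEP.OUT.ATTRS = FALSE))
  roots <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(starts))) {
    x <- starts[i, ]
    ok <- FALSE
    for (it in 1:100) {
      f <- grn_rhs(x, params, sig0)
      if (max(abs(f)) < tol) { ok <- TRUE; break }
      J <- grn_jacobian(x, params, sig0)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      # damp overly large steps to stay in the physical octant
      sc <- min(1, 2 / max(abs(step)))
      x <- x + sc * step
      if (any(x < -0.5) || any(x > 50)) break
      x[x < 0] <- 0
    }
    if (ok && all(x >= 0)) roots <- rbind(roots, as.numeric(x))
  }
  if (nrow(roots) == 0L) {
    warning("no fixed point found from any start")
    return(data.frame(blimp1 = numeric(0), bcl6 = numeric(0),
                      irf4 = numeric(0), stable = logical(0),
                      residual = numeric(0)))
  }
  keep <- rep(TRUE, nrow(roots))
  for (i in seq_len(nrow(roots)))
    if (keep[i] && i < nrow(roots))
      for (j in seq(i + 1L, nrow(roots)))
        if (keep[j] && max(abs(roots[i, ] - roots[j, ])) < 1e-6)
          keep[j] <- FALSE
  roots <- roots[keep, , drop = FALSE]
  stable <- apply(roots, 1, function(x) {
    ev <- eigen(grn_jacobian(x, params, sig0), only.values = TRUE)$values
    all(Re(ev) < 0)
  })
  resid <- apply(roots, 1, function(x) max(abs(grn_rhs(x, params, sig0))))
  out <- data.frame(blimp1 = roots[, 1], bcl6 = roots[, 2], irf4 = roots[, 3],
                    stable = stable, residual = resid)
  out[order(out$blimp1), , drop = FALSE]
}

#' Classify a TF state as BLIMP1-high or BLIMP1-low
#'
#' BLIMP1-high (at or above the plasma-cell differentiation threshold) marks
#' commitment to the plasma-cell program; the comparison is inclusive.
#'
#' @param state TF state.
#' @param thresholds \code{\link{fate_thresholds}}.
#' @return \code{"BLIMP1-high"} or \code{"BLIMP1-low"}.
#' @export
classify_tf_state <- function(state, thresholds = fate_thresholds()) {
  validate_tf_state(state)
  if (state[[1]] >= thresholds$blimp1_pc_threshold) "BLIMP1-high"
  else "BLIMP1-low"
}

#' First time BLIMP1 reaches a threshold
#'
#' Integrates the autonomous network (zero signals) and reports the first time
#' the BLIMP1 component reaches \code{threshold}, refined by bisection between
#' integration steps to within 0.01 h. Returns 0 if the state is already at or
#' above the threshold and \code{Inf} if the threshold is not reached within
#' \code{max_hours}.
#'
#' @param state Initial TF state.
#' @param params \code{\link{grn_parameters}}.
#' @param threshold BLIMP1 threshold (model units), default 8.
#' @param max_hours Search horizon (h).
#' @param dt Integration step (h).
#' @return Crossing time in hours, or \code{Inf}.
#' @export
time_to_threshold <- function(state, params = grn_parameters(), threshold = 8,
                              max_hours = 504, dt = 0.05) {
  validate_tf_state(state)
  if (max_hours <= 0) stop("max_hours must be > 0")
  if (state[[1]] >= threshold) return(0)
  n <- as.integer(ceiling(max_hours / dt))
  m <- grn_traj_cpp(as.numeric(state), param_vec(params), 0, 0, dt, n)
  i <- which(m[, 1] >= threshold)[1]
  if (is.na(i)) return(Inf)
  # bracket [t_lo, t_hi] around the crossing, bisect on a single RK4 step
  t_lo <- (i - 2) * dt
  s_lo <- m[i - 1, ]
  lo <- 0; hi <- dt
  q <- param_vec(params)
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    val <- grn_traj_cpp(s_lo, q, 0, 0, mid, 1L)[2, 1]
    if (val >= threshold) hi <- mid else lo <- mid
  }
  t_lo + (lo + hi) / 2
}

#' Simulate asymmetric division of a plasmablast into two daughters
#'
#' The standalone network experiment: a parent cell (default the plasmablast
#' state (8, 2, 2)) divides with polarity levels \code{levels} =
#' (L_BLIMP1, L_BCL6, L_IRF4); daughter 1 starts at \code{levels * parent},
#' daughter 2 at \code{(1 - levels) * parent}. Both daughters are integrated
#' with zero signals until the network is steady (max-norm of the rates below
#' \code{steady_tol}) or 504 h have elapsed, and their terminal states are
#' classified as BLIMP1-high or BLIMP1-low.
#'
#' @param levels Numeric polarity triple, each in \code{[0.5, 1]}.
#' @param parent Parent TF state (default \code{tf_state(8, 2, 2)}).
#' @param params \code{\link{grn_parameters}}.
#' @param thresholds \code{\link{fate_thresholds}}.
#' @param dt Integration step (h).
#' @param steady_tol Steady-state tolerance on the rates (units/h).
#' @return List with elements \code{daughter1}, \code{daughter2} (trajectory
#'   data frames as \code{\link{grn_integrate}}), \code{classification}
#'   (character 2-vector) and \code{terminal} (2 x 3 matrix of final states).
#' @export
#' @examples
#' dx <- daughter_experiment(c(1, 1, 1))
#' dx$classification  # one BLIMP1-high daughter, one BLIMP1-low
daughter_experiment <- function(levels, parent = tf_state(8, 2, 2),
                                params = grn_parameters(),
                                thresholds = fate_thresholds(),
                                dt = 0.05, steady_tol = 1e-6) {
  levels <- as.numeric(levels)
  if (length(levels) != 3L || any(levels < 0.5) || any(levels > 1))
    stop("polarity levels must be three values in [0.5, 1]")
  validate_tf_state(parent)
  run_until_steady <- function(s0) {
    chunk <- 24
    t0 <- 0
    parts <- list()
    state <- as.numeric(s0)
    repeat {
      tr <- grn_integrate(state, params, signal_input(), dt, chunk)
      tr$time_h <- tr$time_h + t0
      parts[[length(parts) + 1L]] <- if (t0 == 0) tr else tr[-1L, ]
      state <- as.numeric(tr[nrow(tr), c("blimp1", "bcl6", "irf4")])
      t0 <- t0 + chunk
      f <- grn_rhs(state, params, signal_input())
      if (max(abs(f)) < steady_tol || t0 >= 504) break
    }
    do.call(rbind, parts)
  }
  d1 <- run_until_steady(levels * as.numeric(parent))
  d2 <- run_until_steady((1 - levels) * as.numeric(parent))
  term <- rbind(daughter1 = as.numeric(d1[nrow(d1), -1L]),
                daughter2 = as.numeric(d2[nrow(d2), -1L]))
  colnames(term) <- c("blimp1", "bcl6", "irf4")
  list(daughter1 = d1, daughter2 = d2,
       classification = c(daughter1 = classify_tf_state(term[1, ], thresholds),
                          daughter2 = classify_tf_state(term[2, ], thresholds)),
       terminal = term)
}
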