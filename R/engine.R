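#' Germinal-center engine configuration
#'
#' Population, timing and signalling parameters of the two-compartment GC
#' simulation. Time is in hours throughout; the reaction lasts 21 days
#' (504 h) by default.
#'
#' Centroblasts (CBs) divide in the dark zone with somatic hypermutation and
#' then differentiate over \code{cb_to_cc_delay} hours into centrocytes (CCs)
#' in the light zone. A CC occupies a free FDC site, tests it at
#' \code{fdc_test_rate} per hour during a \code{collect_window}-hour contact
#' (each test captures one antigen portion with probability equal to the
#' cell's affinity and refreshes the apoptosis clock, with BcR signalling
#' active); a CC that captured antigen then competes for Tfh help for up to
#' \code{tfh_window} hours. Each of the \code{n_tfh} Tfh cells helps one
#' contacted CC per step, preferring the highest retained antigen load (ties
#' broken towards the lowest cell id); help delivers the CD40 signal scaled by
#' affinity. A CC accumulating \code{tfh_help_needed} hours of contact is
#' selected and recycles to the DZ as a CB with \code{recycle_divisions}
#' divisions; a CC that ends its collection window empty-handed or exhausts
#' its Tfh search window unselected undergoes apoptosis, as does any CC whose
#' \code{cc_lifetime} clock expires while queueing.
#'
#' @param duration Length of the reaction (h).
#' @param dt Engine step (h).
#' @param sample_cadence Observable sampling interval (h).
#' @param n_founders Number of founder cells.
#' @param founder_window Founder influx window (h).
#' @param founder_divisions Divisions in the founder expansion phase.
#' @param cb_cycle Centroblast cell-cycle length (h).
#' @param cycle_jitter Uniform relative jitter on the cycle length.
#' @param recycle_divisions Divisions granted to a selected, recycled CB.
#' @param cb_to_cc_delay CB-to-CC differentiation time (h).
#' @param cc_lifetime Apoptosis clock of a centrocyte (h).
#' @param await_lifetime Survival time of a retained (awaiting) cell that has
#'   finished dividing with a partial antigen load but has not reached the
#'   BLIMP1 threshold (h); it dies by neglect when the clock expires.
#' @param collect_window FDC contact window (h).
#' @param fdc_test_rate Antigen test rate during collection (1/h).
#' @param tfh_window Tfh search window (h).
#' @param tfh_help_needed Contact hours required for positive selection.
#' @param resources \code{\link{lz_resources}}.
#' @param grn \code{\link{grn_parameters}} (includes the BcR and CD40 signal
#'   scales \code{bcr0} and \code{cd0}).
#' @param grn_dt GRN integration substep (h).
#' @param shape \code{\link{affinity_model}}.
#' @param p_mut Hypermutation probability per daughter per division.
#' @param founder_dist Founder genotype distance range.
#' @param thresholds \code{\link{fate_thresholds}}.
#' @param seed Default RNG seed for \code{\link{gc_run}}.
#' @return An object of class \code{engine_config}.
#' @export
engine_config <- function(duration = 504, dt = 0.1, sample_cadence = 1,
                          n_founders = 100, founder_window = 92,
                          founder_divisions = 6L,
                          cb_cycle = 7, cycle_jitter = 0.1,
                          recycle_divisions = 2L, cb_to_cc_delay = 2,
                          cc_lifetime = 10, await_lifetime = 24,
                          collect_window = 3,
                          fdc_test_rate = 2, tfh_window = 3,
                          tfh_help_needed = 0.7,
                          resources = lz_resources(),
                          grn = grn_parameters(), grn_dt = 0.05,
                          shape = affinity_model(), p_mut = 0.5,
                          founder_dist = c(5, 10),
                          thresholds = fate_thresholds(), seed = 1L) {
  if (duration <= 0 || dt <= 0) stop("duration and dt must be > 0")
  if (duration < dt) stop("duration must be at least dt")
  stopifnot(inherits(resources, "lz_resources"),
            inherits(grn, "grn_params"),
            inherits(shape, "affinity_model"),
            inherits(thresholds, "fate_thresholds"))
  if (p_mut < 0 || p_mut > 1) stop("p_mut must lie in [0, 1]")
  structure(list(duration = duration, dt = dt,
                 sample_cadence = sample_cadence,
                 n_founders = as.integer(n_founders),
                 founder_window = founder_window,
                 founder_divisions = as.integer(founder_divisions),
                 cb_cycle = cb_cycle, cycle_jitter = cycle_jitter,
                 recycle_divisions = as.integer(recycle_divisions),
                 cb_to_cc_delay = cb_to_cc_delay,
                 cc_lifetime = cc_lifetime, await_lifetime = await_lifetime,
                 collect_window = collect_window,
                 fdc_test_rate = fdc_test_rate, tfh_window = tfh_window,
                 tfh_help_needed = tfh_help_needed, resources = resources,
                 grn = grn, grn_dt = grn_dt, shape = shape, p_mut = p_mut,
                 founder_dist = founder_dist, thresholds = thresholds,
                 seed = as.integer(seed)),
            class = "engine_config")
}

#' @export
print.engine_config <- function(x, ...) {
  cat(sprintf("<engine_config> %g h, dt=%g h, %d founders (%d divisions)\n",
              x$duration, x$dt, x$n_founders, x$founder_divisions))
  cat(sprintf("  LZ: %d FDC sites, %d Tfh; CC life %g h; help needed %g h\n",
              x$resources$n_fdc_sites, x$resources$n_tfh, x$cc_lifetime,
              x$tfh_help_needed))
  cat(sprintf("  signals: bcr0=%g cd0=%g; seed %d\n",
              x$grn$bcr0, x$grn$cd0, x$seed))
  invisible(x)
}

#' Run a full germinal-center simulation
#'
#' Executes the 21-day event loop: founder influx and expansion, dark-zone
#' division with hypermutation and (for recycled cells) asymmetric division
#' of antigen and transcription factors, CB-to-CC differentiation, FDC antigen
#' collection, Tfh-help competition, positive selection and recycling,
#' apoptosis, output-cell fate dispatch and egress. Every live cell's TF
#' network is integrated each step with its current BcR/CD40 signal input.
#'
#' Plasma cells exit whenever a cell past its division phase (a finished or
#' differentiating recycled centroblast, an awaiting cell, or a centrocyte)
#' reaches the BLIMP1 threshold; memory B cells exit at division completion
#' when they carry the parent's whole antigen load but are BLIMP1-low.
#'
#' @param config \code{\link{engine_config}}.
#' @param policy \code{\link{division_policy}}.
#' @param seed Integer seed (defaults to \code{config$seed}); a run is fully
#'   deterministic given its seed.
#' @return An object of class \code{gc_run}: a list with \code{timeseries}
#'   (hourly observables: \code{time_h}, \code{cb}, \code{cc_live},
#'   \code{apopt_cum}, \code{pc_cum}, \code{mbc_cum}, \code{await},
#'   \code{pb}, \code{dz_lz_ratio} with \code{Inf} when no live CC exists),
#'   \code{output_cells} (per output cell: \code{exit_time_h}, \code{type}
#'   \code{1=PC, 2=MBC}, \code{ag_status}, \code{blimp1}), \code{selections}
#'   (per positive selection: \code{time_h}, \code{affinity}, \code{ag}),
#'   \code{counters}, \code{config}, \code{policy}, \code{seed}.
#' @export
gc_run <- function(config = engine_config(), policy = division_policy(),
                   seed = config$seed) {
  stopifnot(inherits(config, "engine_config"),
            inherits(policy, "division_policy"))
  cf <- config
  set.seed(as.integer(seed))
  qv <- param_vec(cf$grn)
  thr <- cf$thresholds$blimp1_pc_threshold
  nsub <- max(1L, as.integer(round(cf$dt / cf$grn_dt)))
  nsteps <- as.integer(round(cf$duration / cf$dt))
  se <- max(1L, as.integer(round(cf$sample_cadence / cf$dt)))
  dt <- cf$dt
  n_tfh <- cf$resources$n_tfh
  n_fdc <- cf$resources$n_fdc_sites
  test_p <- min(1, cf$fdc_test_rate * dt)
  coupled <- identical(policy$coupling, "coupled")
  jit <- function(k) cf$cb_cycle *
    stats::runif(k, 1 - cf$cycle_jitter, 1 + cf$cycle_jitter)

  pop <- new_population(4096L, cf$shape$dimension)
  oc <- new_log(c("exit_time_h", "type", "ag_status", "blimp1"))
  sel <- new_log(c("time_h", "affinity", "ag", "blimp1", "bcl6", "irf4"))

  arrivals <- sort(stats::runif(cf$n_founders, 0, cf$founder_window))
  next_f <- 1L

  nsamp <- nsteps %/% se + 1L
  ts <- matrix(0, nsamp, 9)
  colnames(ts) <- c("time_h", "cb", "cc_live", "apopt_cum", "pc_cum",
                    "mbc_cum", "await", "pb", "dz_lz_ratio")
  si <- 0L

  act <- integer(0)  # maintained vector of live cell indices

  take_sample <- function(t) {
    a <- act[pop$alive[act]]
    cb <- sum(pop$stage[a] == STAGE_CB)
    cc <- sum(pop$stage[a] == STAGE_CC)
    aw <- sum(pop$stage[a] == STAGE_AWAIT)
    pb <- sum(pop$p[a] >= thr)
    if (length(a) && (any(!is.finite(pop$p[a])) || any(pop$ag[a] < 0)))
      stop("inconsistent state at t=", t,
           ": non-finite TF concentration or negative antigen load")
    if (length(a) != pop$created - pop$div_parents - pop$apopt -
        pop$n_pc - pop$n_mbc)
      stop("cell bookkeeping violated at t=", t)
    si <<- si + 1L
    ts[si, ] <<- c(t, cb, cc, pop$apopt, pop$n_pc, pop$n_mbc, aw, pb,
                   if (cc == 0L) Inf else cb / cc)
  }

  kill <- function(i) {
    pop$alive[i] <- FALSE
    pop$cdaff[i] <- 0
    pop$bcr[i] <- FALSE
  }

  egress <- function(i, type, t) {
    if (!length(i)) return(invisible())
    kill(i)
    log_add(oc, rep(t, length(i)), rep(type, length(i)),
            as.numeric(pop$ag[i] > 0), pop$p[i])
    if (type == 1) pop$n_pc <- pop$n_pc + length(i)
    else pop$n_mbc <- pop$n_mbc + length(i)
  }

  for (step in seq_len(nsteps) - 1L) {
    t <- step * dt
    if (step %% se == 0L) take_sample(t)
    t_next <- t + dt

    ## founder influx scheduled within (t, t + dt]
    while (next_f <= cf$n_founders && arrivals[next_f] <= t_next) {
      i <- pop_reserve(pop, 1L)
      g <- founder_gene(cf$shape, cf$founder_dist)
      pop$alive[i] <- TRUE; pop$stage[i] <- STAGE_CB; pop$phase[i] <- PH_NONE
      pop$p[i] <- 0; pop$b[i] <- 5; pop$r[i] <- 0
      pop$ag[i] <- 0; pop$agfull[i] <- FALSE
      pop$divleft[i] <- cf$founder_divisions; pop$recycled[i] <- FALSE
      pop$cclock[i] <- jit(1L); pop$delay[i] <- 0; pop$born[i] <- t_next
      pop$gene[i, ] <- g; pop$aff[i] <- affinity(g, cf$shape)
      act <- c(act, i)
      next_f <- next_f + 1L
    }

    act <- act[pop$alive[act]]
    alive <- act
    if (!length(alive) && next_f > cf$n_founders) {
      ## reaction over; keep sampling zeros
      next
    }

    ## (1) GRN update for every live B cell with its current signals
    if (length(alive)) {
      st <- grn_update_cpp(pop$p[alive], pop$b[alive], pop$r[alive],
                           as.numeric(pop$bcr[alive]), pop$cdaff[alive],
                           qv, dt, nsub)
      pop$p[alive] <- st[, 1]; pop$b[alive] <- st[, 2]; pop$r[alive] <- st[, 3]
    }

    ## (2) centroblast cycle and division
    cyc <- alive[pop$stage[alive] == STAGE_CB & pop$delay[alive] <= 0 &
                   pop$divleft[alive] > 0L]
    if (length(cyc)) {
      pop$cclock[cyc] <- pop$cclock[cyc] - dt
      due <- cyc[pop$cclock[cyc] <= 0]
      nd <- length(due)
      if (nd) {
        rec <- pop$recycled[due]
        ## division-mode draws (founder-phase divisions are symmetric)
        if (coupled) {
          u <- stats::runif(nd)
          ag_asym <- (u < policy$p_ag) & rec
          tf_asym <- (u < policy$p_tf) & rec
        } else {
          ag_asym <- (stats::runif(nd) < policy$p_ag) & rec
          tf_asym <- (stats::runif(nd) < policy$p_tf) & rec
        }
        hi_first <- stats::runif(nd) < 0.5

        lp <- ifelse(tf_asym, policy$l_blimp1, 0.5)
        lb <- ifelse(tf_asym, policy$l_bcl6, 0.5)
        lr <- ifelse(tf_asym, policy$l_irf4, 0.5)
        lag <- ifelse(ag_asym, policy$l_ag, 0.5)

        p_hi <- pop$p[due] * lp; p_lo <- pop$p[due] - p_hi
        b_hi <- pop$b[due] * lb; b_lo <- pop$b[due] - b_hi
        r_hi <- pop$r[due] * lr; r_lo <- pop$r[due] - r_hi
        a_hi <- pop$ag[due] * lag; a_lo <- pop$ag[due] - a_hi
        full_hi <- pop$agfull[due] & ag_asym & (policy$l_ag == 1) &
          pop$ag[due] > 0

        ## interleave so daughter pairs stay adjacent; high side by fair coin
        ord1 <- ifelse(hi_first, 1, 2); ord2 <- 3 - ord1
        d_p <- numeric(2 * nd); d_b <- d_p; d_r <- d_p; d_ag <- d_p
        d_full <- logical(2 * nd)
        i1 <- 2 * seq_len(nd) - 2 + ord1   # slot of high-side daughter
        i2 <- 2 * seq_len(nd) - 2 + ord2
        d_p[i1] <- p_hi; d_p[i2] <- p_lo
        d_b[i1] <- b_hi; d_b[i2] <- b_lo
        d_r[i1] <- r_hi; d_r[i2] <- r_lo
        d_ag[i1] <- a_hi; d_ag[i2] <- a_lo
        d_full[i1] <- full_hi

        par2 <- rep(due, each = 2L)
        genes <- pop$gene[par2, , drop = FALSE]
        shm <- mutate_bcr_rows(genes, cf$p_mut)
        newaff <- affinity(shm$position, cf$shape)

        idx <- pop_reserve(pop, 2L * nd)
        pop$alive[idx] <- TRUE
        pop$stage[idx] <- STAGE_CB; pop$phase[idx] <- PH_NONE
        pop$p[idx] <- d_p; pop$b[idx] <- d_b; pop$r[idx] <- d_r
        pop$ag[idx] <- d_ag; pop$agfull[idx] <- d_full
        pop$divleft[idx] <- rep(pop$divleft[due] - 1L, each = 2L)
        pop$recycled[idx] <- rep(rec, each = 2L)
        pop$cclock[idx] <- jit(2L * nd)
        pop$delay[idx] <- 0; pop$born[idx] <- t_next
        pop$gene[idx, ] <- shm$position
        pop$aff[idx] <- newaff
        pop$mutc[idx] <- rep(pop$mutc[due], each = 2L) + shm$mutated
        pop$alive[due] <- FALSE
        pop$div_parents <- pop$div_parents + nd

        ## (3) fate dispatch for recycled daughters that finished dividing
        fin <- idx[pop$recycled[idx] & pop$divleft[idx] == 0L]
        if (length(fin)) {
          code <- fate_codes(pop$p[fin], pop$ag[fin], pop$agfull[fin], thr)
          egress(fin[code == 1L], 1, t_next)
          egress(fin[code == 2L], 2, t_next)
          ret <- fin[code == 3L]
          if (length(ret)) {
            pop$ag[ret] <- 0; pop$agfull[ret] <- FALSE
            pop$delay[ret] <- cf$cb_to_cc_delay
          }
          aw <- fin[code == 4L]
          if (length(aw)) {
            pop$stage[aw] <- STAGE_AWAIT
            pop$life[aw] <- cf$await_lifetime
          }
        }
        ## (4a) founder-phase daughters that finished expanding differentiate
        ffin <- idx[!pop$recycled[idx] & pop$divleft[idx] == 0L]
        if (length(ffin)) pop$delay[ffin] <- cf$cb_to_cc_delay
        act <- c(act[pop$alive[act]], idx[pop$alive[idx]])
        alive <- act
      }
    }

    ## (4b) CB -> CC differentiation and DZ -> LZ transfer
    dif <- alive[pop$stage[alive] == STAGE_CB & pop$delay[alive] > 0]
    if (length(dif)) {
      pop$delay[dif] <- pop$delay[dif] - dt
      done <- dif[pop$delay[dif] <= 0]
      if (length(done)) {
        pop$stage[done] <- STAGE_CC; pop$phase[done] <- PH_SEEK_FDC
        pop$life[done] <- cf$cc_lifetime; pop$help[done] <- 0
        pop$pclock[done] <- 0
      }
    }

    ## (5) FDC antigen collection
    coll <- alive[pop$stage[alive] == STAGE_CC & pop$phase[alive] == PH_COLLECT]
    if (length(coll)) {
      pop$pclock[coll] <- pop$pclock[coll] - dt
      tested <- stats::runif(length(coll)) < test_p
      capt <- coll[tested & stats::runif(length(coll)) < pop$aff[coll]]
      if (length(capt)) {
        pop$ag[capt] <- pop$ag[capt] + 1
        pop$life[capt] <- cf$cc_lifetime
      }
      fin <- coll[pop$pclock[coll] <= 0]
      if (length(fin)) {
        hungry <- fin[pop$ag[fin] <= 0]
        fed <- fin[pop$ag[fin] > 0]
        if (length(hungry)) { kill(hungry); pop$apopt <- pop$apopt + length(hungry) }
        if (length(fed)) {
          pop$phase[fed] <- PH_SEEK_TFH
          pop$pclock[fed] <- cf$tfh_window
        }
      }
    }
    seekers <- alive[pop$alive[alive] & pop$stage[alive] == STAGE_CC &
                       pop$phase[alive] == PH_SEEK_FDC]
    n_coll <- sum(pop$alive[alive] & pop$phase[alive] == PH_COLLECT &
                    pop$stage[alive] == STAGE_CC)
    free <- n_fdc - n_coll
    if (free > 0L && length(seekers)) {
      adm <- seekers[seq_len(min(free, length(seekers)))]
      pop$phase[adm] <- PH_COLLECT
      pop$pclock[adm] <- cf$collect_window
    }
    ## BcR signalling is active while in FDC contact
    pop$bcr[alive] <- FALSE
    incontact <- alive[pop$alive[alive] & pop$stage[alive] == STAGE_CC &
                         pop$phase[alive] == PH_COLLECT]
    pop$bcr[incontact] <- TRUE

    ## (6) Tfh allocation: each Tfh helps the contacted CC with the highest
    ## retained antigen (ties to the lowest id)
    cand <- alive[pop$alive[alive] & pop$stage[alive] == STAGE_CC &
                    pop$phase[alive] == PH_SEEK_TFH]
    pop$cdaff[alive] <- 0
    selected <- integer(0)
    if (length(cand)) {
      pop$pclock[cand] <- pop$pclock[cand] - dt
      helped <- cand[order(-pop$ag[cand], cand)][seq_len(min(n_tfh, length(cand)))]
      pop$help[helped] <- pop$help[helped] + dt
      pop$cdaff[helped] <- pop$aff[helped]
      ## (7) positive selection and recycling
      selected <- helped[pop$help[helped] >= cf$tfh_help_needed - 1e-9]
      if (length(selected)) {
        log_add(sel, rep(t_next, length(selected)), pop$aff[selected],
                pop$ag[selected], pop$p[selected], pop$b[selected],
                pop$r[selected])
        pop$stage[selected] <- STAGE_CB; pop$phase[selected] <- PH_NONE
        pop$recycled[selected] <- TRUE
        pop$divleft[selected] <- cf$recycle_divisions
        pop$cclock[selected] <- jit(length(selected))
        pop$delay[selected] <- 0
        pop$agfull[selected] <- pop$ag[selected] > 0
        pop$help[selected] <- 0
        pop$cdaff[selected] <- 0; pop$bcr[selected] <- FALSE
      }
      expired <- setdiff(cand[pop$pclock[cand] <= 0], selected)
      if (length(expired)) {
        kill(expired); pop$apopt <- pop$apopt + length(expired)
      }
    }

    ## (8) apoptosis of centrocytes whose clock expired
    cc <- alive[pop$alive[alive] & pop$stage[alive] == STAGE_CC]
    if (length(cc)) {
      pop$life[cc] <- pop$life[cc] - dt
      dead <- cc[pop$life[cc] <= 0]
      if (length(dead)) { kill(dead); pop$apopt <- pop$apopt + length(dead) }
    }
    ## retained cells that fail to differentiate die by neglect
    aw <- alive[pop$alive[alive] & pop$stage[alive] == STAGE_AWAIT]
    if (length(aw)) {
      pop$life[aw] <- pop$life[aw] - dt
      dead <- aw[pop$life[aw] <= 0]
      if (length(dead)) { kill(dead); pop$apopt <- pop$apopt + length(dead) }
    }

    ## (9) plasma-cell egress: any cell past its division phase that has
    ## reached the BLIMP1 threshold leaves the GC
    elig <- alive[pop$alive[alive] &
                    (pop$stage[alive] == STAGE_AWAIT |
                       pop$stage[alive] == STAGE_CC |
                       (pop$stage[alive] == STAGE_CB &
                          pop$delay[alive] > 0))]
    if (length(elig)) egress(elig[pop$p[elig] >= thr], 1, t_next)
  }
  take_sample(nsteps * dt)

  ocd <- log_df(oc)
  res <- list(timeseries = as.data.frame(ts[seq_len(si), , drop = FALSE]),
              output_cells = ocd,
              selections = log_df(sel),
              counters = list(created = pop$created,
                              division_parents = pop$div_parents,
                              apoptosed = pop$apopt,
                              pc = pop$n_pc, mbc = pop$n_mbc,
                              alive_final = sum(pop$alive[seq_len(pop$n)])),
              config = cf, policy = policy, seed = as.integer(seed))
  class(res) <- "gc_run"
  res
}

#' @export
print.gc_run <- function(x, ...) {
  cnt <- x$counters
  cat(sprintf("<gc_run> seed %d, %g h: %d PCs, %d MBCs (%d cells created)\n",
              x$seed, max(x$timeseries$time_h), cnt$pc, cnt$mbc, cnt$created))
  fin <- utils::tail(x$timeseries, 1)
  cat(sprintf("  final: %d CB, %d live CC, DZ-to-LZ ratio %s\n",
              fin$cb, fin$cc_live, format(fin$dz_lz_ratio, digits = 3)))
  invisible(x)
}
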