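#' Light-zone resources
#'
#' The light zone is modeled as two capacity-limited contact processes rather
#' than a spatial lattice: a pool of FDC antigen sites (each hosting one
#' collecting centrocyte at a time) and a pool of Tfh cells (each helping one
#' contacted centrocyte per step, preferring the cell with the most
#' internalized antigen).
#'
#' @param n_fdc_sites Number of concurrent FDC collection sites.
#' @param n_tfh Number of Tfh cells.
#' @return An object of class \code{lz_resources}.
#' @export
lz_resources <- function(n_fdc_sites = 600, n_tfh = 30) {
  if (n_fdc_sites < 0 || n_tfh < 0) stop("resource counts must be >= 0")
  structure(list(n_fdc_sites = as.integer(n_fdc_sites),
                 n_tfh = as.integer(n_tfh)),
            class = "lz_resources")
}

#' Create a founder centroblast
#'
#' Founders enter the dark zone with the BCL6-high TF state (BLIMP1 = 0,
#' BCL6 = 5, IRF4 = 0), no internalized antigen, a receptor genotype sampled
#' away from the shape-space optimum, and a full budget of founder divisions.
#' Uses R's global RNG stream.
#'
#' @param id Integer cell identifier.
#' @param founder_divisions Number of divisions in the founder expansion.
#' @param model \code{\link{affinity_model}}.
#' @param dist_range Founder distance range passed to
#'   \code{\link{founder_gene}}.
#' @return A list describing the cell (fields \code{id}, \code{stage},
#'   \code{zone}, \code{tf}, \code{gene}, \code{retained_ag},
#'   \code{divisions_left}, \code{recycled}, \code{cc_phase}, \code{clock}).
#' @export
make_founder <- function(id = 1L, founder_divisions = 6L,
                         model = affinity_model(), dist_range = c(5, 10)) {
  list(id = as.integer(id), stage = "CB", zone = "DZ",
       tf = tf_state(0, 5, 0),
       gene = founder_gene(model, dist_range),
       retained_ag = 0, divisions_left = as.integer(founder_divisions),
       recycled = FALSE, cc_phase = "none", clock = 0)
}

#' Antigen positivity of a cell
#'
#' @param cell A cell list with field \code{retained_ag}.
#' @return \code{TRUE} iff the cell carries a strictly positive antigen load.
#' @export
is_ag_positive <- function(cell) {
  isTRUE(cell$retained_ag > 0)
}

# ---- internal vectorized population store ---------------------------------
# Stages: 1 = CB (dark zone; dividing or differentiating towards CC),
#         2 = CC (light zone), 3 = awaiting differentiation in the DZ
#         (finished recycled CB with a partial antigen load, BLIMP1-low).
# CC phases: 0 none, 1 seeking_fdc, 2 collecting, 3 seeking_tfh.
STAGE_CB <- 1L; STAGE_CC <- 2L; STAGE_AWAIT <- 3L
PH_NONE <- 0L; PH_SEEK_FDC <- 1L; PH_COLLECT <- 2L; PH_SEEK_TFH <- 3L

new_population <- function(cap, dim) {
  e <- new.env(parent = emptyenv())
  e$cap <- cap; e$n <- 0L; e$dim <- dim
  num <- function() numeric(cap)
  int <- function() integer(cap)
  lgl <- function() logical(cap)
  e$alive <- lgl(); e$stage <- int(); e$phase <- int()
  e$p <- num(); e$b <- num(); e$r <- num()
  e$ag <- num(); e$agfull <- lgl()
  e$divleft <- int(); e$recycled <- lgl()
  e$pclock <- num(); e$life <- num(); e$help <- num()
  e$cclock <- num(); e$delay <- num(); e$born <- num()
  e$bcr <- lgl(); e$cdaff <- num()
  e$aff <- num(); e$mutc <- int()
  e$gene <- matrix(0, cap, dim)
  # audit counters
  e$created <- 0L; e$div_parents <- 0L; e$apopt <- 0L
  e$n_pc <- 0L; e$n_mbc <- 0L
  e
}

pop_grow <- function(pop, need) {
  while (pop$cap < need) {
    newcap <- pop$cap * 2L
    for (f in c("alive", "stage", "phase", "p", "b", "r", "ag", "agfull",
                "divleft", "recycled", "pclock", "life", "help", "cclock",
                "delay", "born", "bcr", "cdaff", "aff", "mutc")) {
      v <- pop[[f]]
      length(v) <- newcap
      if (is.numeric(pop[[f]])) v[is.na(v)] <- 0
      if (is.logical(pop[[f]])) v[is.na(v)] <- FALSE
      pop[[f]] <- v
    }
    g <- matrix(0, newcap, pop$dim)
    g[seq_len(pop$n), ] <- pop$gene[seq_len(pop$n), ]
    pop$gene <- g
    pop$cap <- newcap
  }
  invisible(pop)
}

# Reserve k new rows and return their indices (row index doubles as cell id;
# ids are therefore unique and increase with creation order).
pop_reserve <- function(pop, k) {
  pop_grow(pop, pop$n + k)
  idx <- pop$n + seq_len(k)
  pop$n <- pop$n + k
  pop$created <- pop$created + k
  idx
}

# simple growable event log (columns fixed at creation)
new_log <- function(cols, cap = 1024L) {
  e <- new.env(parent = emptyenv())
  e$cols <- cols; e$n <- 0L; e$cap <- cap
  for (cl in cols) e[[cl]] <- numeric(cap)
  e
}

log_add <- function(lg, ...) {
  vals <- list(...)
  k <- length(vals[[1L]])
  if (k == 0L) return(invisible(lg))
  while (lg$cap < lg$n + k) {
    for (cl in lg$cols) { v <- lg[[cl]]; length(v) <- lg$cap * 2L; lg[[cl]] <- v }
    lg$cap <- lg$cap * 2L
  }
  i <- lg$n + seq_len(k)
  for (j in seq_along(lg$cols)) lg[[lg$cols[j]]][i] <- vals[[j]]
  lg$n <- lg$n + k
  invisible(lg)
}

log_df <- function(lg) {
  out <- lapply(lg$cols, function(cl) lg[[cl]][seq_len(lg$n)])
  names(out) <- lg$cols
  as.data.frame(out)
}
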