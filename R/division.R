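#' Asymmetric-division policy
#'
#' A division of a recycled centroblast distributes internalized antigen (Ag)
#' and the three transcription factors between the two daughters. For each
#' species class the division is asymmetric with probability \code{p_*}; an
#' asymmetric division gives one daughter the fraction \code{l_*} (the
#' polarity level) of the parent's amount and the other daughter the
#' complement \code{1 - l_*}. A symmetric division is the degenerate case
#' L = 0.5. When Ag and TFs are asymmetric in the same division the larger
#' shares go to the same daughter.
#'
#' @param p_ag,p_tf Probabilities of asymmetric division for antigen and for
#'   the transcription factors, in \code{[0, 1]}.
#' @param l_ag Polarity level for antigen, in \code{[0.5, 1]}.
#' @param l_blimp1,l_bcl6,l_irf4 Per-factor polarity levels, in
#'   \code{[0.5, 1]}.
#' @param coupling One of \code{"coupled"} (a single Bernoulli draw decides
#'   both classes; requires \code{p_ag == p_tf}), \code{"uncoupled"}
#'   (independent draws), \code{"tf_only"}, \code{"ag_only"}, \code{"none"}.
#' @return An object of class \code{division_policy}.
#' @export
#' @examples
#' # reference scenario: asymmetric antigen, symmetric TFs
#' division_policy(p_ag = 0.72, p_tf = 0, l_ag = 1, coupling = "ag_only")
division_policy <- function(p_ag = 0, p_tf = 0, l_ag = 0.5,
                            l_blimp1 = 0.5, l_bcl6 = 0.5, l_irf4 = 0.5,
                            coupling = c("none", "coupled", "uncoupled",
                                         "tf_only", "ag_only")) {
  coupling <- match.arg(coupling)
  pr <- c(p_ag = p_ag, p_tf = p_tf)
  lv <- c(l_ag = l_ag, l_blimp1 = l_blimp1, l_bcl6 = l_bcl6, l_irf4 = l_irf4)
  if (any(!is.finite(c(pr, lv))))
    stop("policy values must be finite")
  if (any(pr < 0 | pr > 1))
    stop("asymmetry probabilities must lie in [0, 1]")
  if (any(lv < 0.5 | lv > 1))
    stop("polarity levels must lie in [0.5, 1]")
  if (coupling == "coupled" && p_ag != p_tf)
    stop("coupling = \"coupled\" requires p_ag == p_tf")
  if (coupling == "tf_only" && p_ag != 0)
    stop("coupling = \"tf_only\" requires p_ag == 0")
  if (coupling == "ag_only" && p_tf != 0)
    stop("coupling = \"ag_only\" requires p_tf == 0")
  if (coupling == "none" && (p_ag != 0 || p_tf != 0))
    stop("coupling = \"none\" requires p_ag == p_tf == 0")
  structure(list(p_ag = p_ag, p_tf = p_tf, l_ag = l_ag,
                 l_blimp1 = l_blimp1, l_bcl6 = l_bcl6, l_irf4 = l_irf4,
                 coupling = coupling),
            class = "division_policy")
}

#' @export
print.division_policy <- function(x, ...) {
  cat(sprintf(paste0("<division_policy> %s; P_Ag=%g P_TF=%g; L_Ag=%g ",
                     "L_BLIMP1=%g L_BCL6=%g L_IRF4=%g\n"),
              x$coupling, x$p_ag, x$p_tf, x$l_ag, x$l_blimp1, x$l_bcl6,
              x$l_irf4))
  invisible(x)
}

#' Draw the mode of one division
#'
#' Decides, for a single division event, whether antigen and the TFs divide
#' symmetrically or asymmetrically and which daughter is the high side. Under
#' \code{coupling = "coupled"} one Bernoulli draw decides both classes;
#' otherwise the two classes draw independently. The high side is a fair coin
#' and is shared: when both classes are asymmetric, the high Ag daughter is
#' also the high TF daughter.
#'
#' Uses R's global RNG stream; seed it for reproducibility.
#'
#' @param policy A \code{\link{division_policy}}.
#' @return A list with elements \code{ag_mode}, \code{tf_mode} (each
#'   \code{"symmetric"} or \code{"asymmetric"}) and \code{high_side} (1 or 2).
#' @export
draw_division_mode <- function(policy) {
  stopifnot(inherits(policy, "division_policy"))
  if (policy$coupling == "coupled") {
    asym <- stats::runif(1) < policy$p_ag
    ag_asym <- asym; tf_asym <- asym
  } else {
    ag_asym <- stats::runif(1) < policy$p_ag
    tf_asym <- stats::runif(1) < policy$p_tf
  }
  list(ag_mode = if (ag_asym) "asymmetric" else "symmetric",
       tf_mode = if (tf_asym) "asymmetric" else "symmetric",
       high_side = if (stats::runif(1) < 0.5) 1L else 2L)
}

#' Split parent concentrations between two daughters
#'
#' Applies the polarity levels of \code{policy} to the parent's TF state and
#' antigen load according to a drawn division mode. The high-side daughter
#' receives fraction L of each species, the other daughter \code{1 - L};
#' symmetric mode uses L = 0.5 for every species of that class. Daughter
#' amounts always sum exactly to the parent amount.
#'
#' @param parent_tf Parent TF state (numeric length 3).
#' @param parent_ag Parent antigen load (portions, >= 0).
#' @param outcome A division mode as returned by
#'   \code{\link{draw_division_mode}}.
#' @param policy A \code{\link{division_policy}}.
#' @return List with elements \code{daughter1} and \code{daughter2}, each a
#'   list with \code{tf} (numeric length 3) and \code{ag}.
#' @export
#' @examples
#' pol <- division_policy(p_ag = 1, p_tf = 1, l_ag = 1, l_blimp1 = 0.75,
#'                        l_bcl6 = 1, l_irf4 = 1, coupling = "uncoupled")
#' out <- list(ag_mode = "asymmetric", tf_mode = "asymmetric", high_side = 1L)
#' split_concentrations(c(8, 2, 2), 4, out, pol)
split_concentrations <- function(parent_tf, parent_ag, outcome, policy) {
  validate_tf_state(parent_tf)
  stopifnot(parent_ag >= 0)
  l_tf <- if (identical(outcome$tf_mode, "asymmetric"))
    c(policy$l_blimp1, policy$l_bcl6, policy$l_irf4) else rep(0.5, 3)
  l_ag <- if (identical(outcome$ag_mode, "asymmetric")) policy$l_ag else 0.5
  hi <- outcome$high_side
  tf_hi <- as.numeric(parent_tf) * l_tf
  tf_lo <- as.numeric(parent_tf) - tf_hi
  ag_hi <- parent_ag * l_ag
  ag_lo <- parent_ag - ag_hi
  d <- list(list(tf = tf_hi, ag = ag_hi), list(tf = tf_lo, ag = ag_lo))
  if (hi == 2L) d <- d[c(2L, 1L)]
  names(d) <- c("daughter1", "daughter2")
  d
}
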