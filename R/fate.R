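#' Output-cell fate rules
#'
#' @param thresholds \code{\link{fate_thresholds}}.
#' @param annotate_pb Whether plasmablast annotation is recorded in run logs.
#' @return An object of class \code{fate_rule_config}.
#' @export
fate_rule_config <- function(thresholds = fate_thresholds(),
                             annotate_pb = TRUE) {
  stopifnot(inherits(thresholds, "fate_thresholds"))
  structure(list(thresholds = thresholds, annotate_pb = isTRUE(annotate_pb)),
            class = "fate_rule_config")
}

# Vectorized fate decision shared by the scalar API and the engine.
# Codes: 1 = PC, 2 = MBC, 3 = return_to_CC, 4 = await_pc.
fate_codes <- function(blimp1, ag, ag_full, thr) {
  code <- integer(length(blimp1))
  pc <- blimp1 >= thr
  mbc <- !pc & ag_full & ag > 0
  ret <- !pc & !mbc & ag == 0
  code[pc] <- 1L
  code[mbc] <- 2L
  code[ret] <- 3L
  code[!pc & !mbc & !ret] <- 4L
  code
}

#' Classify the fate of a recycled centroblast that finished dividing
#'
#' Applied when a recycled centroblast completes its last division:
#' \itemize{
#'   \item BLIMP1 at or above the plasma-cell threshold: \code{"PC"}
#'     (irrespective of antigen status, which is recorded but not used);
#'   \item otherwise, if the cell inherited the parent's whole antigen load
#'     through asymmetric division(s) (\code{ag_full}) and carries antigen:
#'     \code{"MBC"};
#'   \item otherwise, if it carries no antigen: \code{"return_to_CC"} -- the
#'     cell re-enters the light zone as a centrocyte with its antigen load
#'     reset to zero, gaining no advantage in further rounds of selection;
#'   \item otherwise (a partial antigen load from a symmetric split):
#'     \code{"await_pc"} -- the cell is retained in the dark zone and exits as
#'     a plasma cell if and when BLIMP1 later reaches the threshold.
#' }
#'
#' @param cell A list with numeric \code{blimp1} (or a \code{tf} triple),
#'   \code{retained_ag}, logical \code{recycled} and integer
#'   \code{divisions_left}; optional logical \code{ag_full} (defaults to
#'   \code{retained_ag > 0}).
#' @param config A \code{\link{fate_rule_config}}.
#' @return One of \code{"PC"}, \code{"MBC"}, \code{"return_to_CC"},
#'   \code{"await_pc"}.
#' @export
#' @examples
#' classify_fate(list(blimp1 = 9, retained_ag = 0, recycled = TRUE,
#'                    divisions_left = 0))            # "PC"
#' classify_fate(list(blimp1 = 3, retained_ag = 2, recycled = TRUE,
#'                    divisions_left = 0))            # "MBC"
classify_fate <- function(cell, config = fate_rule_config()) {
  if (!isTRUE(cell$recycled) || !identical(as.integer(cell$divisions_left), 0L))
    stop("classify_fate applies only to recycled centroblasts that have ",
         "finished dividing")
  blimp1 <- if (!is.null(cell$blimp1)) cell$blimp1 else cell$tf[[1]]
  ag <- cell$retained_ag
  ag_full <- if (!is.null(cell$ag_full)) isTRUE(cell$ag_full) else ag > 0
  thr <- config$thresholds$blimp1_pc_threshold
  c("PC", "MBC", "return_to_CC", "await_pc")[
    fate_codes(blimp1, ag, ag_full, thr)]
}

#' Plasmablast annotation
#'
#' A live germinal-center B cell is annotated as a plasmablast (PB) when its
#' BLIMP1 level is at or above the plasma-cell threshold but it has not yet
#' left the reaction as an output cell.
#'
#' @param cell A list with \code{blimp1} (or \code{tf}) and \code{stage}.
#' @param thresholds \code{\link{fate_thresholds}}.
#' @return Logical.
#' @export
annotate_pb <- function(cell, thresholds = fate_thresholds()) {
  blimp1 <- if (!is.null(cell$blimp1)) cell$blimp1 else cell$tf[[1]]
  blimp1 >= thresholds$blimp1_pc_threshold &&
    !(cell$stage %in% c("PC", "MBC"))
}
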