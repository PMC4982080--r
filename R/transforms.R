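#' Logit and inverse-logit transforms
#'
#' Proportion-scale estimates are pooled on the logit scale,
#' \eqn{\mathrm{logit}(p) = \ln(p/(1-p))}, and back-transformed for
#' interpretation. These are thin wrappers around [stats::qlogis()] and
#' [stats::plogis()], which are numerically stable in the tails.
#'
#' @param p Proportion(s) in (0, 1).
#' @param x Value(s) on the logit scale.
#' @return `logit()` returns log-odds; `expit()` returns proportions.
#' @examples
#' logit(0.5)        # 0
#' expit(logit(0.21))
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
expit <- function(x) stats::plogis(x)

# Canonical label for a time frame: "1" for a point analysis, "1-6" for change.
frame_label <- function(frame) paste(frame, collapse = "-")
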