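#' Gradient-harmonized L1 loss
#'
#' The training loss for yield regression under location imbalance. For
#' residual \eqn{d_i = \hat y_i - y_i} the per-sample loss is
#' \deqn{|d_i| + \frac{d_i}{\sqrt{d_i^2 + \alpha^2}}}
#' averaged over samples: an L1 term plus a bounded harmonizing term that
#' saturates for large residuals, tempering the pull of locations whose
#' predictions are far off (typically the under-sampled ones). As
#' \eqn{\alpha \to \infty} the harmonizing term vanishes and the loss reduces
#' to plain L1.
#'
#' The `"signed"` variant uses \eqn{d_i} in the numerator as printed in the
#' loss definition; since the signed term rewards under-prediction slightly,
#' an `"absolute"` variant replacing \eqn{d_i} by \eqn{|d_i|} is available
#' behind the `variant` switch.
#'
#' @param pred,true Equal-length numeric vectors of predictions and targets.
#' @param alpha Positive harmonizing constant (default 0.3).
#' @param variant `"signed"` (default) or `"absolute"`.
#' @return The mean loss, a single number.
#' @examples
#' ghm_loss(1, 0, alpha = 0.3)  # 1 + 1/sqrt(1.09)
#' @export
ghm_loss <- function(pred, true, alpha = 0.3, variant = c("signed", "absolute")) {
  variant <- match.arg(variant)
  check_loss_inputs(pred, true)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a single positive number", call. = FALSE)
  }
  d <- pred - true
  num <- if (variant == "signed") d else abs(d)
  mean(abs(d) + num / sqrt(d^2 + alpha^2))
}

#' Mean absolute and mean squared losses
#'
#' Plain L1 (mean absolute residual) and L2 (mean squared residual) losses,
#' used as ablation baselines for the gradient-harmonized loss.
#'
#' @inheritParams ghm_loss
#' @return The mean loss, a single number.
#' @export
l1_loss <- function(pred, true) {
  check_loss_inputs(pred, true)
  mean(abs(pred - true))
}

#' @rdname l1_loss
#' @export
l2_loss <- function(pred, true) {
  check_loss_inputs(pred, true)
  mean((pred - true)^2)
}

check_loss_inputs <- function(pred, true) {
  if (length(pred) == 0L) stop("empty input", call. = FALSE)
  if (length(pred) != length(true)) {
    stop("pred and true must have equal length", call. = FALSE)
  }
  invisible(NULL)
}

# internal: numeric code for the C++ core
loss_kind_code <- function(kind) {
  match(kind, c("l1", "l2", "ghm")) - 1L
}
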