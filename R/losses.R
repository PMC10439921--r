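#' Multi-task patch-classifier loss components
#'
#' Pure numeric implementations of the four task losses used to train the
#' patch-wise classifier — sigmoid focal loss (classification), mean
#' absolute error (regression), mean squared error (reconstruction), binary
#' cross-entropy (segmentation) — and the auto-weighted total loss that
#' combines them with trainable per-task weights. All losses are
#' non-negative means over the batch; predictions interpreted as
#' probabilities are clipped to `[eps, 1 - eps]`.
#'
#' `focal_loss` modes: `"literal"` evaluates
#' `-(1/n) * sum beta * (1 - yhat)^gamma * log(yhat)` over positive-labeled
#' items only (the one-sided published form); `"two_sided"` adds the
#' symmetric negative-class term `(1 - beta) * yhat^gamma * log(1 - yhat)`.
#' On positive-labeled batches, two-sided focal with `gamma = 0, beta = 1`
#' reduces exactly to binary cross-entropy.
#'
#' @param y numeric targets (0/1 for focal/bce, real for mae/mse).
#' @param y_hat numeric predictions, same length as `y` (probabilities for
#'   focal/bce).
#' @param beta positive-class weight (default 0.5).
#' @param gamma focusing exponent >= 0 (default 2).
#' @param mode `"literal"` or `"two_sided"` (see above).
#' @param eps probability clipping bound (default 1e-7).
#' @return scalar loss >= 0.
#' @export
#' @examples
#' focal_loss(1, 0.5)                       # 0.5 * 0.25 * log(2)
#' bce_loss(1, 0.5)                         # log(2)
focal_loss <- function(y, y_hat, beta = 0.5, gamma = 2,
                       mode = c("literal", "two_sided"), eps = 1e-7) {
  mode <- match.arg(mode)
  stopifnot(length(y) == length(y_hat), beta > 0, beta <= 1, gamma >= 0)
  if (length(y) == 0L) stop("empty batch")
  n <- length(y)
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  pos <- -sum(y * beta * (1 - p)^gamma * log(p)) / n
  if (mode == "literal") return(pos)
  neg <- -sum((1 - y) * (1 - beta) * p^gamma * log(1 - p)) / n
  pos + neg
}

#' @rdname focal_loss
#' @export
mae_loss <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) > 0)
  mean(abs(y - y_hat))
}

#' @rdname focal_loss
#' @export
mse_loss <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) > 0)
  mean((y - y_hat)^2)
}

#' @rdname focal_loss
#' @export
bce_loss <- function(y, y_hat, eps = 1e-7) {
  stopifnot(length(y) == length(y_hat), length(y) > 0)
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Trainable task weights for the auto-weighted total loss
#'
#' Each auxiliary task (regression `reg`, reconstruction `aut`,
#' segmentation `seg`) carries a trainable log-weight `alpha`, initialized
#' to 0 so all tasks start with equal weight; the classification loss is
#' always weighted 1. A task can instead be frozen out (contributes
#' nothing) or given a fixed manual weight (e.g. 0.75 for segmentation),
#' reproducing the task-ablation configurations.
#'
#' @param alpha_reg,alpha_aut,alpha_seg trainable log-weights (default 0).
#' @param variant `"standard"`: task i contributes
#'   `exp(-alpha_i) * L_i + alpha_i` — the homoscedastic-uncertainty
#'   auto-weighting form, whose `+alpha` terms genuinely prevent the
#'   effective weights from collapsing (optimum at `exp(-alpha) = 1/L`).
#'   `"literal"`: `exp(+alpha_i) * L_i + alpha_i`, kept for fidelity
#'   experiments; note this objective is unbounded below in alpha.
#' @return An `fna_task_weights` object.
#' @export
task_weights <- function(alpha_reg = 0, alpha_aut = 0, alpha_seg = 0,
                         variant = c("standard", "literal")) {
  variant <- match.arg(variant)
  alphas <- c(reg = alpha_reg, aut = alpha_aut, seg = alpha_seg)
  stopifnot(all(is.finite(alphas)))
  structure(list(alphas = alphas,
                 mode = c(reg = "trainable", aut = "trainable", seg = "trainable"),
                 manual = c(reg = NA_real_, aut = NA_real_, seg = NA_real_),
                 variant = variant),
            class = "fna_task_weights")
}

#' @rdname task_weights
#' @param tasks character subset of `c("reg", "aut", "seg")` to keep active;
#'   tasks not listed are frozen at weight 0 (they contribute nothing to the
#'   total loss, and no regularizer term is added for them).
#' @param manual_weights optional named numeric vector of fixed weights for
#'   listed tasks (e.g. `c(seg = 0.75)`); fixed-weight tasks contribute
#'   `w * L` with no trainable alpha.
#' @export
task_ablation_config <- function(tasks = character(),
                                 manual_weights = NULL,
                                 variant = c("standard", "literal")) {
  stopifnot(all(tasks %in% c("reg", "aut", "seg")))
  tw <- task_weights(variant = match.arg(variant))
  for (t in c("reg", "aut", "seg")) {
    if (!(t %in% tasks)) {
      tw$mode[[t]] <- "frozen"
    } else if (!is.null(manual_weights) && t %in% names(manual_weights)) {
      tw$mode[[t]] <- "manual"
      tw$manual[[t]] <- manual_weights[[t]]
    }
  }
  tw
}

#' Auto-weighted total loss
#'
#' Combines the four task losses under the task-weight configuration:
#' classification always at weight 1; each trainable task contributing
#' `exp(-alpha) * L + alpha` (standard variant) or `exp(+alpha) * L + alpha`
#' (literal variant); manual tasks contributing `w * L`; frozen tasks
#' contributing nothing. With all alphas 0 both variants reduce to the plain
#' sum `L_cls + L_reg + L_aut + L_seg`.
#'
#' @param l_cls,l_reg,l_aut,l_seg component losses (>= 0).
#' @param weights [task_weights()] or [task_ablation_config()] result.
#' @return scalar total loss.
#' @export
total_loss <- function(l_cls, l_reg, l_aut, l_seg, weights = task_weights()) {
  stopifnot(inherits(weights, "fna_task_weights"),
            l_cls >= 0, l_reg >= 0, l_aut >= 0, l_seg >= 0)
  comp <- c(reg = as.numeric(l_reg), aut = as.numeric(l_aut),
            seg = as.numeric(l_seg))
  total <- l_cls
  for (t in names(comp)) {
    total <- total + switch(
      weights$mode[[t]],
      frozen = 0,
      manual = weights$manual[[t]] * comp[[t]],
      trainable = {
        a <- weights$alphas[[t]]
        w <- if (weights$variant == "standard") exp(-a) else exp(a)
        w * comp[[t]] + a
      })
  }
  total
}
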