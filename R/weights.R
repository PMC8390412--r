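#' Kernel parameters for age weighting
#'
#' Bundles the three tunables of the rolling age-weight kernel: the focus age
#' (`center`), the `shoulder` exponent of the raw kernel `1 - |center - age|^shoulder`
#' (controls the flatness of the peak), and the `decay` exponent applied to the
#' min-max-scaled weights (controls how fast weights fall toward zero away
#' from the focus age).
#'
#' @param center Focus age in years (finite numeric scalar).
#' @param shoulder Positive exponent of the raw distance kernel. Default 1.5.
#' @param decay Positive exponent applied to the scaled weights. Default 25.
#'
#' @return An object of class `kernel_params`: a list with elements `center`,
#'   `shoulder`, `decay`.
#' @examples
#' kernel_params(center = 25)
#' @export
kernel_params <- function(center, shoulder = 1.5, decay = 25) {
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center))
    stop("`center` must be a finite numeric scalar")
  if (!is.numeric(shoulder) || length(shoulder) != 1L || !is.finite(shoulder) ||
      shoulder <= 0)
    stop("`shoulder` must be a positive finite scalar")
  if (!is.numeric(decay) || length(decay) != 1L || !is.finite(decay) || decay <= 0)
    stop("`decay` must be a positive finite scalar")
  structure(list(center = center, shoulder = shoulder, decay = decay),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("Age-weight kernel: center = %g, shoulder = %g, decay = %g\n",
              x$center, x$shoulder, x$decay))
  invisible(x)
}

#' Stage 1: raw shoulder kernel
#'
#' Computes the raw (unscaled) kernel value `1 - |center - age|^shoulder` for
#' each observation age. The value is exactly 1 at the focus age and may be
#' arbitrarily negative far from it; stages 2 and 3 rescale it into `[0, 1]`.
#'
#' @param ages Numeric vector of observation ages in years (finite, non-empty).
#' @param params A [kernel_params()] object.
#' @return Numeric vector of raw kernel values, same length as `ages`.
#' @export
weight_stage1 <- function(ages, params) {
  stopifnot(inherits(params, "kernel_params"))
  if (length(ages) == 0L) stop("`ages` must be non-empty")
  if (!is.numeric(ages) || any(!is.finite(ages)))
    stop("`ages` must be finite numeric")
  1 - abs(params$center - ages)^params$shoulder
}

#' Stage 2: min-max scaling
#'
#' Rescales the stage-1 kernel values linearly so that the maximum maps to 1
#' and the minimum to 0. The scaling is data-relative: it depends on the
#' observed age range, so the same kernel parameters give different absolute
#' weights on datasets with different age spans.
#'
#' @param w1 Numeric vector of stage-1 kernel values (non-empty).
#' @return Numeric vector in `[0, 1]`.
#' @details When all entries of `w1` are equal the rescaling is undefined
#'   (this happens when every observation shares one age); an error is thrown
#'   and the caller is expected to fall back to uniform weight 1, as
#'   [compute_weights()] does.
#' @export
weight_stage2 <- function(w1) {
  if (length(w1) == 0L) stop("`w1` must be non-empty")
  rng <- range(w1)
  if (rng[1] == rng[2])
    stop("degenerate input: all stage-1 weights equal (max == min); ",
         "min-max scaling is undefined. This occurs when all observations ",
         "share a single age; assign uniform weight 1 in that case.")
  (w1 - rng[1]) / (rng[2] - rng[1])
}

#' Stage 3: decay exponent
#'
#' Raises the min-max-scaled weights to the `decay` power. 0 and 1 are fixed
#' points; values strictly between shrink, the more so the larger `decay`,
#' narrowing the effective window around the focus age.
#'
#' @param w2 Numeric vector with entries in `[0, 1]`.
#' @param decay Positive exponent.
#' @return Numeric vector in `[0, 1]`.
#' @export
weight_stage3 <- function(w2, decay) {
  if (!is.numeric(decay) || length(decay) != 1L || !is.finite(decay) || decay <= 0)
    stop("`decay` must be a positive finite scalar")
  if (any(w2 < 0 | w2 > 1, na.rm = TRUE))
    stop("`w2` entries must lie in [0, 1]")
  w2^decay
}

#' Compute observation weights for one focus age
#'
#' Chains the three weighting stages: raw shoulder kernel, min-max scaling,
#' decay exponent. Observations at the age(s) nearest the focus age receive
#' weight exactly 1; the observation most distant from the focus age receives
#' weight exactly 0; weights are non-increasing in the distance from the
#' focus age.
#'
#' @param ages Numeric vector of observation ages in years.
#' @param params A [kernel_params()] object.
#' @return An object of class `weight_vector`: a data frame with columns
#'   `age`, `w1` (raw kernel), `w2` (min-max scaled), `weight` (final), plus
#'   the kernel parameters in attribute `"params"`.
#' @details A dataset where every observation has the same age makes the
#'   min-max step undefined; the function then assigns uniform weight 1 to
#'   all rows and emits a warning.
#' @examples
#' w <- compute_weights(12:70, kernel_params(center = 25))
#' w$weight[w$age == 25]  # exactly 1
#' @export
compute_weights <- function(ages, params) {
  w1 <- weight_stage1(ages, params)
  if (length(unique(w1)) == 1L) {
    warning("all observations share one age; assigning uniform weight 1")
    w2 <- rep(1, length(ages))
    w3 <- w2
  } else {
    w2 <- weight_stage2(w1)
    w3 <- weight_stage3(w2, params$decay)
  }
  structure(
    data.frame(age = ages, w1 = w1, w2 = w2, weight = w3),
    params = params,
    class = c("weight_vector", "data.frame")
  )
}
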