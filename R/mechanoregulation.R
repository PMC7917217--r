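# Biophysical stimulus S = gamma/a + v/b and tissue-fate classification.

#' Stimulus parameters
#'
#' The empirically derived constants of the biophysical stimulus
#' S = gamma/a + v/b (gamma octahedral shear strain in percent, v fluid
#' velocity in mm/s) and the fate thresholds: S < 0.01 bone resorption,
#' 0.01 <= S < 1 bone formation, 1 <= S < 3 cartilage formation, S >= 3
#' fibrous tissue formation (intervals closed on the left).
#'
#' @param a strain constant, percent.
#' @param b fluid velocity constant, mm/s.
#' @param thresholds the three fate boundaries (resorption/bone,
#'   bone/cartilage, cartilage/fibrous).
#' @return list of class `stimulus_params`.
#' @export
stimulus_params <- function(a = 3.75, b = 3e-3,
                            thresholds = c(0.01, 1, 3)) {
  if (a <= 0 || b <= 0) stop("a and b must be positive")
  if (!(length(thresholds) == 3 && all(diff(c(0, thresholds)) > 0)))
    stop("thresholds must satisfy 0 < t0 < t1 < t2")
  out <- list(a = a, b = b, thresholds = thresholds)
  class(out) <- "stimulus_params"
  out
}

#' Fate class labels, in increasing-stimulus order
#' @export
fate_levels <- function() c("resorption", "bone", "cartilage", "fibrous")

#' Compute the biophysical stimulus
#'
#' S = gamma/a + v/b elementwise. `state` is a `mechano_state` (matrices
#' `gamma` in percent and `v` in mm/s) as returned by [solve_step()] or
#' [surrogate_field()].
#'
#' @param state a `mechano_state`, or a list with `gamma` and `v` matrices.
#' @param params a [stimulus_params()].
#' @return matrix of S values (same shape as `gamma`).
#' @export
compute_stimulus <- function(state, params = stimulus_params()) {
  g <- state$gamma; v <- state$v
  if (any(g < 0) || any(v < 0)) stop("gamma and v must be non-negative")
  if (any(g > 1000))
    warning("gamma > 1000%: is the strain given as a fraction instead of percent?")
  g / params$a + v / params$b
}

#' Classify stimulus into tissue fates
#'
#' Maps S to the unique fate class: `[0, t0)` resorption, `[t0, t1)` bone,
#' `[t1, t2)` cartilage, `[t2, Inf)` fibrous (boundaries closed on the left).
#'
#' @param S numeric vector/matrix of stimulus values (>= 0).
#' @param params a [stimulus_params()].
#' @return character vector/matrix of fate labels.
#' @export
classify_stimulus <- function(S, params = stimulus_params()) {
  if (any(S < 0)) stop("S must be non-negative")
  t <- params$thresholds
  f <- ifelse(S < t[1], "resorption",
       ifelse(S < t[2], "bone",
       ifelse(S < t[3], "cartilage", "fibrous")))
  if (is.matrix(S)) f <- matrix(f, nrow(S), ncol(S)) else f
  f
}

#' Integer coding of fate maps (for CSV/VTK export)
#'
#' resorption = 0, bone = 1, cartilage = 2, fibrous = 3.
#' @param fate character fate matrix.
#' @return integer matrix.
#' @export
fate_codes <- function(fate) {
  m <- matrix(match(fate, fate_levels()) - 1L,
              nrow(as.matrix(fate)), ncol(as.matrix(fate)))
  m
}
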