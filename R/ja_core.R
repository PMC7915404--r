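#' Bounded-confidence pair interaction
#'
#' The pairwise kernel of the Jager-Amblard family. With attitude gap
#' `g = |x_i - x_j|`:
#' * `g < d1` (assimilation): each attitude moves toward the partner by its
#'   own coefficient, `x_i' = x_i + mu_i (x_j - x_i)` and symmetrically;
#' * `g > d2` (rejection): each attitude moves away,
#'   `x_i' = x_i - mu_i (x_j - x_i)`;
#' * otherwise the pair is neutral and nothing changes.
#'
#' Both updates use the pre-interaction values (simultaneous pair update) and
#' the thresholds are strict, so boundary gaps `g = d1` or `g = d2` are
#' neutral. Results are clipped to \[-1, 1\].
#'
#' @param x_i,x_j Attitudes in \[-1, 1\].
#' @param mu_i,mu_j Opinion-change coefficients in \[0, 1\].
#' @param d1 Assimilation threshold.
#' @param d2 Rejection threshold (`d1 < d2`).
#' @return A list with elements `x_i`, `x_j` (updated attitudes) and `kind`
#'   (`"assimilated"`, `"rejected"` or `"neutral"`).
#' @export
ja_interact <- function(x_i, x_j, mu_i, mu_j, d1, d2) {
  if (d1 >= d2) stop("require d1 < d2", call. = FALSE)
  gap <- abs(x_i - x_j)
  if (gap < d1) {
    kind <- "assimilated"
    xi <- x_i + mu_i * (x_j - x_i)
    xj <- x_j + mu_j * (x_i - x_j)
  } else if (gap > d2) {
    kind <- "rejected"
    xi <- x_i - mu_i * (x_j - x_i)
    xj <- x_j - mu_j * (x_i - x_j)
  } else {
    return(list(x_i = x_i, x_j = x_j, kind = "neutral"))
  }
  list(x_i = min(1, max(-1, xi)), x_j = min(1, max(-1, xj)), kind = kind)
}

#' Classic Jager-Amblard interaction
#'
#' The homogeneous variant used as a pure-polarization baseline: both agents
#' share one fixed coefficient `mu` instead of the heterogeneous
#' per-agent coefficients. Under assimilation with equal coefficients the
#' pair mean is conserved exactly.
#'
#' @inheritParams ja_interact
#' @param mu Shared coefficient in \[0, 1\].
#' @return As [ja_interact()].
#' @export
classic_ja_interact <- function(x_i, x_j, mu, d1, d2) {
  ja_interact(x_i, x_j, mu, mu, d1, d2)
}

#' Opinion-convergence check
#'
#' The simulation stop rule: interaction has settled once the summed squared
#' one-step attitude change
#' \deqn{\sum_i (x_i(t) - x_i(t-1))^2 \le \mathrm{tol}}
#' with default tolerance 0.1.
#'
#' @param x_prev,x_curr Attitude vectors of equal length.
#' @param tol Tolerance (default 0.1).
#' @return `TRUE` if converged.
#' @export
has_converged <- function(x_prev, x_curr, tol = 0.1) {
  if (length(x_prev) != length(x_curr))
    stop("attitude vectors must have equal length", call. = FALSE)
  sum((x_curr - x_prev)^2) <= tol
}
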