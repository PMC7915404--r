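#' Communicating willingness
#'
#' Propensity of an agent to spread the information it holds, increasing in
#' the extremity of its attitude and in the external recognition its opinion
#' has received:
#' \deqn{P = (|x| - 1) e^{1 - m} + 1.}
#' For recognition `m >= 1` the value lies in `[|x|, 1]`; when an agent's
#' opinion has been repeatedly rejected, `m` can fall below 1 and the
#' willingness can turn negative, which is what drives the
#' disengagement-by-rejection route of the state machine.
#'
#' @param x Attitude in \[-1, 1\] (vectorized).
#' @param m External recognition degree (vectorized; initial value 1).
#' @return Willingness value(s).
#' @export
communicating_willingness <- function(x, m) {
  if (any(abs(x) > 1 + 1e-12, na.rm = TRUE))
    stop("attitudes must lie in [-1, 1]", call. = FALSE)
  (abs(x) - 1) * exp(1 - m) + 1
}

#' Degree-based conservatism profile
#'
#' Assigns each node a conservatism (resistance to opinion change) inversely
#' proportional to its degree, scaled so the population mean equals `T0`:
#' \deqn{T_i = N \, T_0 \, k_i^{-1} / \sum_l k_l^{-1},}
#' then clipped to \[0, 1\]. Low-degree agents, who see little of the
#' network, are the most conservative; hubs the least. Isolated nodes are
#' assigned `T0` directly (they never interact, so the value is inert) and
#' are excluded from the normalization.
#'
#' @param net An `opinion_network`.
#' @param T0 Target mean conservatism in \[0, 1\].
#' @param clip Clip the profile to \[0, 1\] (default). The unclipped profile
#'   has mean exactly `T0`.
#' @return Numeric vector of length `net$n`.
#' @export
conservatism_profile <- function(net, T0, clip = TRUE) {
  stopifnot(inherits(net, "opinion_network"))
  if (T0 < 0 || T0 > 1) stop("T0 must lie in [0, 1]", call. = FALSE)
  tc <- rep(T0, net$n)
  con <- net$deg > 0L
  if (any(con)) {
    inv <- 1 / net$deg[con]
    tc[con] <- sum(con) * T0 * inv / sum(inv)
  }
  if (clip) tc <- pmin(1, pmax(0, tc))
  tc
}

#' Mainstream-degree update
#'
#' Each agent tracks a running belief about which opinion sign dominates the
#' network: `w_plus` and `w_minus` (summing to 1) are its perceived
#' mainstream degrees of the positive and negative camps. After interacting
#' with a positively-opinionated partner, `w_plus` gains `gamma` and
#' `w_minus` loses `gamma`; a negative partner does the opposite. The pair is
#' clipped jointly so both components stay in \[0, 1\] and the sum remains
#' exactly 1.
#'
#' @param w_plus,w_minus Current mainstream degrees, summing to 1.
#' @param partner_sign `+1` for a positive-opinion partner, `-1` for a
#'   negative one (attitude 0 counts as positive).
#' @param gamma Step size per interaction, in (0, 0.5\].
#' @return Numeric vector `c(w_plus, w_minus)`.
#' @export
update_mainstream <- function(w_plus, w_minus, partner_sign, gamma) {
  if (abs(w_plus + w_minus - 1) > 1e-9)
    stop("mainstream degrees must sum to 1", call. = FALSE)
  wp <- w_plus + sign(partner_sign) * gamma
  wp <- min(1, max(0, wp))
  c(wp, 1 - wp)
}

#' Conformity
#'
#' Linear transform of a mainstream degree into the strength with which the
#' agent conforms to that camp: `C = 2 w - 1`, clipped below at 0 so a camp
#' perceived as the minority (`w < 0.5`) exerts no conformity pull. At the
#' initial `w = 0.5` the conformity is 0, so opinions cannot move until
#' interaction history accumulates.
#'
#' @param w Mainstream degree in \[0, 1\] (vectorized).
#' @return Conformity in \[0, 1\].
#' @export
conformity <- function(w) {
  if (any(w < -1e-12 | w > 1 + 1e-12))
    stop("mainstream degree must lie in [0, 1]", call. = FALSE)
  pmax(0, 2 * w - 1)
}

#' Opinion-change coefficient
#'
#' Per-interaction susceptibility of an agent: the product of tie strength,
#' openness and conformity toward the partner's camp,
#' \deqn{\mu = (1 + E_{ij}) (1 - T_i) C^{\pm},}
#' where `C^+` is used when the partner's attitude is `>= 0` and `C^-`
#' otherwise. The `1 + E` factor keeps weak ties from silencing the exchange
#' entirely; the result is clipped to \[0, 1\].
#'
#' @param emb Embeddedness of the interacting pair, in \[0, 1\].
#' @param cons Conservatism of the focal agent, in \[0, 1\].
#' @param conf_pos,conf_neg Conformity of the focal agent toward the positive
#'   and negative camps.
#' @param x_partner The partner's attitude (selects the camp).
#' @return Coefficient in \[0, 1\].
#' @export
opinion_change_coefficient <- function(emb, cons, conf_pos, conf_neg,
                                       x_partner) {
  cc <- if (x_partner >= 0) conf_pos else conf_neg
  min(1, max(0, (1 + emb) * (1 - cons) * cc))
}

#' External-recognition update
#'
#' The recognition degree `m` rises when an agent's opinion is assimilated by
#' an interaction partner and falls when it is rejected; neutral encounters
#' leave it unchanged. It starts at 1 and is unbounded below, so a string of
#' rejections can push the communicating willingness negative and force the
#' agent into the immune state. Set `floor = 1` to forbid values below 1
#' (which makes the rejection-driven exit unreachable).
#'
#' @param m Current recognition degree.
#' @param outcome One of `"assimilated"`, `"rejected"`, `"neutral"`.
#' @param floor Optional lower bound on the updated value.
#' @return Updated recognition degree.
#' @export
update_recognition <- function(m, outcome = c("assimilated", "rejected",
                                              "neutral"),
                               floor = NULL) {
  outcome <- match.arg(outcome)
  m2 <- switch(outcome, assimilated = m + 1, rejected = m - 1, neutral = m)
  if (!is.null(floor)) m2 <- max(floor, m2)
  m2
}
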