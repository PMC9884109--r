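#' Specify a dual-system learning agent
#'
#' The agent consists of two parallel learning systems. Each system
#' represents states either individually (IR: one tabular value per
#' state) or through the successor representation (SR: each state encoded
#' by its estimated discounted future occupancies of all states, with a
#' learned linear weight vector). Each system has its own learning rates
#' for positive (non-negative) and negative temporal-difference reward
#' prediction errors (TD-RPEs); a system learning mainly from positive
#' TD-RPEs is called appetitive, one learning mainly from negative
#' TD-RPEs aversive. The arithmetic mean of the two system-specific state
#' values is the integrated value, used both for softmax action selection
#' and for computing the single TD-RPE shared by both systems.
#'
#' @param rep1,rep2 Representation of system 1 and 2: `"SR"` or `"IR"`.
#' @param alpha1_pos,alpha1_neg Learning rates of system 1 for
#'   non-negative and negative TD-RPEs, each in \[0, 1\].
#' @param alpha2_pos,alpha2_neg Same for system 2.
#' @param alpha_sr Learning rate for the TD update of SR features
#'   (default 0.05).
#' @param beta Softmax inverse temperature (exploitation over
#'   exploration), non-negative.
#' @param gamma Time discount factor in \[0, 1\].
#' @return An object of class `agent_spec`.
#' @examples
#' agent_spec("SR", "IR", 0.8, 0.2, 0.2, 0.8)
#' @export
agent_spec <- function(rep1 = "SR", rep2 = "IR",
                       alpha1_pos = 0.5, alpha1_neg = 0.5,
                       alpha2_pos = 0.5, alpha2_neg = 0.5,
                       alpha_sr = 0.05, beta = 5, gamma = 0.7) {
  rep1 <- match.arg(rep1, c("SR", "IR"))
  rep2 <- match.arg(rep2, c("SR", "IR"))
  rates <- c(
    alpha1_pos = alpha1_pos, alpha1_neg = alpha1_neg,
    alpha2_pos = alpha2_pos, alpha2_neg = alpha2_neg,
    alpha_sr = alpha_sr
  )
  for (nm in names(rates)) {
    v <- rates[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("learning rate `", nm, "` must be a single value in [0, 1]",
        call. = FALSE
      )
    }
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop("`beta` must be a single non-negative value", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1) {
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      rep1 = rep1, rep2 = rep2,
      alpha1_pos = alpha1_pos, alpha1_neg = alpha1_neg,
      alpha2_pos = alpha2_pos, alpha2_neg = alpha2_neg,
      alpha_sr = alpha_sr, beta = beta, gamma = gamma
    ),
    class = "agent_spec"
  )
}

#' Learning rates from a sum and a positive/negative ratio
#'
#' Parameterises a system's pair of learning rates by their sum and the
#' ratio r = alpha+/alpha-: alpha+ = sum * r / (1 + r), alpha- =
#' sum / (1 + r).
#'
#' @param sum_alpha Sum alpha+ + alpha-.
#' @param ratio Ratio alpha+ / alpha-.
#' @return Named numeric vector `c(pos, neg)`.
#' @examples
#' rates_from_ratio(1, 4) # c(pos = 0.8, neg = 0.2)
#' @export
rates_from_ratio <- function(sum_alpha, ratio) {
  c(pos = sum_alpha * ratio / (1 + ratio), neg = sum_alpha / (1 + ratio))
}

#' Initialise the mutable learning state of a dual-system agent
#'
#' IR systems start with all state values 0. SR systems start with all
#' feature occupancies and weights 0, unless an explicit initial SR
#' matrix is supplied (as in the two-stage tasks, where the SR is
#' initialised from the presumed stage-transition structure).
#'
#' @param spec An [agent_spec()].
#' @param n_states Number of states (25 for the grid; number of options
#'   for the two-stage tasks).
#' @param sigma_init Optional initial SR matrix applied to SR systems.
#' @return An object of class `dual_agent`.
#' @export
agent_init <- function(spec, n_states = 25L, sigma_init = NULL) {
  init_system <- function(rep) {
    if (rep == "SR") {
      sigma <- if (is.null(sigma_init)) {
        matrix(0, n_states, n_states)
      } else {
        stopifnot(nrow(sigma_init) == n_states, ncol(sigma_init) == n_states)
        sigma_init
      }
      list(rep = "SR", sigma = sigma, w = numeric(n_states))
    } else {
      list(rep = "IR", V = numeric(n_states))
    }
  }
  structure(
    list(
      spec = spec, n_states = as.integer(n_states),
      sys1 = init_system(spec$rep1), sys2 = init_system(spec$rep2)
    ),
    class = "dual_agent"
  )
}

#' System-specific value of a state
#'
#' For an IR system this is the stored tabular value; for an SR system it
#' is the inner product of the state's SR feature row with the weight
#' vector ([sr_value()]).
#'
#' @param sys A system state (element `sys1` or `sys2` of a
#'   `dual_agent`).
#' @param s State index.
#' @return The system-specific value.
#' @export
system_value <- function(sys, s) {
  if (sys$rep == "SR") sr_value(sys, s) else sys$V[s]
}

#' SR system value: inner product of SR features with the weights
#'
#' @param sys An SR system state with matrix `sigma` and weights `w`.
#' @param s State index.
#' @return `sum_j w_j * sigma(s, j)`.
#' @export
sr_value <- function(sys, s) {
  sum(sys$sigma[s, ] * sys$w)
}

#' Integrated state value of the dual-system agent
#'
#' @param agent A `dual_agent`.
#' @param s State index (vectorised).
#' @return The arithmetic mean of the two system-specific values.
#' @export
integrated_value <- function(agent, s) {
  vapply(
    s,
    function(si) (system_value(agent$sys1, si) + system_value(agent$sys2, si)) / 2,
    numeric(1)
  )
}

#' Softmax action selection
#'
#' Selects among options with probabilities proportional to
#' `exp(beta * value)`, numerically stabilised by subtracting the maximum
#' value before exponentiation (identical result in exact arithmetic).
#' One uniform variate is drawn against the cumulative probabilities in
#' the given option order.
#'
#' @param values Finite values of the available options (at least one).
#' @param beta Inverse temperature.
#' @return A list with `choice` (index into `values`) and `probs`.
#' @examples
#' set.seed(1)
#' softmax_select(c(0, 0.2), beta = 5)$probs # c(0.2689, 0.7311)
#' @export
softmax_select <- function(values, beta) {
  if (length(values) == 0L) stop("no options to select from", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  wts <- exp(beta * (values - max(values)))
  p <- wts / sum(wts)
  u <- runif(1)
  cp <- cumsum(p)
  choice <- which(u <= cp)[1]
  if (is.na(choice)) choice <- length(values)
  list(choice = choice, probs = p)
}

#' Temporal-difference reward prediction error
#'
#' Non-terminal transition: `delta = gamma * V_next - V_current` (no
#' reward is delivered on ordinary moves). Terminal step (the rewarded
#' state in navigation, a second-stage option in the two-stage tasks):
#' `delta = reward - V_current`, with no successor term.
#'
#' @param v_current Integrated value of the current state.
#' @param v_next Integrated value of the successor (ignored if terminal).
#' @param reward Reward delivered at a terminal step (0 or 1).
#' @param gamma Discount factor.
#' @param terminal Logical.
#' @return The TD-RPE `delta`.
#' @export
value_td_rpe <- function(v_current, v_next, reward, gamma, terminal) {
  if (terminal) reward - v_current else gamma * v_next - v_current
}

#' Valence-dependent effective learning rate
#'
#' `alpha_pos` applies to positive (non-negative) TD-RPEs, including
#' exactly zero; `alpha_neg` to negative ones.
#'
#' @param delta TD-RPE.
#' @param alpha_pos,alpha_neg The two learning rates.
#' @return The effective learning rate.
#' @export
valence_rate <- function(delta, alpha_pos, alpha_neg) {
  if (delta >= 0) alpha_pos else alpha_neg
}

#' Update an IR system's value from a TD-RPE
#'
#' @param sys IR system state.
#' @param s Occupied state.
#' @param delta TD-RPE.
#' @param alpha_eff Effective learning rate from [valence_rate()].
#' @return The updated system state; only `V[s]` changes, by
#'   `alpha_eff * delta`.
#' @export
ir_update <- function(sys, s, delta, alpha_eff) {
  sys$V[s] <- sys$V[s] + alpha_eff * delta
  sys
}

#' TD update of SR features for the occupied state
#'
#' For every state j the SR feature prediction error is
#' `deltaSR_j = 1{s == j} + gamma * sigma(s_next, j) - sigma(s, j)`;
#' at a terminal step the successor term is dropped. Only row `s` of the
#' matrix changes, by `alpha_sr * deltaSR`.
#'
#' @param sys SR system state.
#' @param s Occupied state.
#' @param s_next Successor state (ignored if terminal).
#' @param gamma Discount factor.
#' @param alpha_sr SR feature learning rate.
#' @param terminal Logical.
#' @return The updated system state.
#' @export
sr_feature_update <- function(sys, s, s_next, gamma, alpha_sr, terminal) {
  pre <- sys$sigma[s, ]
  succ <- if (terminal) 0 else gamma * sys$sigma[s_next, ]
  indic <- as.numeric(seq_along(pre) == s)
  sys$sigma[s, ] <- pre + alpha_sr * (indic + succ - pre)
  sys
}

#' Update an SR system's weights from a TD-RPE
#'
#' Credit is spread over the SR features of the occupied state:
#' `w_j <- w_j + alpha_eff * sigma(s, j) * delta` for all j.
#'
#' @param sys SR system state.
#' @param s Occupied state.
#' @param delta TD-RPE.
#' @param alpha_eff Effective learning rate from [valence_rate()].
#' @param features SR feature row to spread credit over; defaults to the
#'   current `sigma[s, ]` — within [agent_step()] the row as already
#'   updated this step.
#' @return The updated system state.
#' @export
sr_weight_update <- function(sys, s, delta, alpha_eff,
                             features = sys$sigma[s, ]) {
  sys$w <- sys$w + alpha_eff * features * delta
  sys
}

#' One learning step of the dual-system agent
#'
#' Orchestrates a single state transition in a fixed order: (1) the
#' TD-RPE is computed from the integrated values using pre-update
#' quantities; (2) each SR system's feature row for the occupied state is
#' updated; (3) each system's values or weights are updated using the
#' shared TD-RPE, its valence-dependent learning rate, and — for SR
#' systems — the feature row as updated in (2). Both systems receive the
#' same TD-RPE.
#'
#' @param agent A `dual_agent`.
#' @param s Occupied state.
#' @param s_next Successor state (may be `NA` if terminal).
#' @param reward Reward (0 or 1) delivered at a terminal step.
#' @param terminal Logical; `TRUE` at the rewarded state (navigation) or
#'   a second-stage option (two-stage tasks).
#' @param update_features Whether SR feature rows are updated this step.
#'   `TRUE` everywhere except the second stage of the two-stage tasks,
#'   whose option rows are terminal and never updated.
#' @return A list with the updated `agent` and the TD-RPE `delta`.
#' @export
agent_step <- function(agent, s, s_next, reward, terminal,
                       update_features = TRUE) {
  spec <- agent$spec
  v_cur <- integrated_value(agent, s)
  v_next <- if (terminal) NA_real_ else integrated_value(agent, s_next)
  delta <- value_td_rpe(v_cur, v_next, reward, spec$gamma, terminal)

  step_system <- function(sys, alpha_pos, alpha_neg) {
    a_eff <- valence_rate(delta, alpha_pos, alpha_neg)
    if (sys$rep == "SR") {
      if (update_features) {
        sys <- sr_feature_update(sys, s, s_next, spec$gamma, spec$alpha_sr,
          terminal = terminal
        )
      }
      sys <- sr_weight_update(sys, s, delta, a_eff)
    } else {
      sys <- ir_update(sys, s, delta, a_eff)
    }
    sys
  }
  agent$sys1 <- step_system(agent$sys1, spec$alpha1_pos, spec$alpha1_neg)
  agent$sys2 <- step_system(agent$sys2, spec$alpha2_pos, spec$alpha2_neg)
  list(agent = agent, delta = delta)
}
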