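# Random-utility choice model: dynamic openness, alternative utilities,
# Gumbel-shock (multinomial-logit) state choice.

#' Utility-model parameters
#'
#' All coefficients of the random-utility choice model. The packaged
#' defaults are the calibrated values used for the baseline scenario; every
#' field can be overridden.
#'
#' \describe{
#'   \item{muCC, muEC}{intrinsic taste for each product (utility units).}
#'   \item{eta}{habituation: utility bonus for a product the agent currently
#'     uses.}
#'   \item{phi}{gain per unit 30-day use frequency of the product.}
#'   \item{wPeer, wSoc}{social-influence weights on close-peer and
#'     population prevalence (utility per unit prevalence).}
#'   \item{alphaPeerMix}{peer share of perceived exposure, in \[0, 1\].}
#'   \item{gammaOpen}{response of openness to perceived exposure.}
#'   \item{thetaCC, thetaEC}{exogenous scenario offsets added to openness.}
#'   \item{crossover}{one-way coupling: e-cigarette exposure raises
#'     cigarette openness, and e-cigarette social utility spills into the
#'     cigarette alternative.}
#'   \item{crossoverOpenness, crossoverUtility}{flags enabling each of the
#'     two crossover channels (both on by default).}
#'   \item{crossoverBidirectional}{if `TRUE`, the coupling also acts
#'     CC to EC with the same strength; off by default — the asymmetric
#'     EC-to-CC direction is the mechanism of interest.}
#'   \item{kappaDual}{fixed cost of the dual alternative (utility units).}
#'   \item{tasteScale}{scale of the i.i.d. Gumbel taste shock; 0 gives a
#'     deterministic argmax.}
#' }
#'
#' Scenario knobs `thetaCC`, `thetaEC` and `crossover` are intended for
#' \[0, 0.3\]; values outside produce a warning, not an error.
#'
#' @param ... named overrides of any field.
#' @return A list of class `utility_params`.
#' @examples
#' p <- default_parameters(crossover = 0.3)
#' @export
default_parameters <- function(...) {
  p <- list(muCC = -9.95, muEC = -6.63, eta = 9.06, phi = 3.09,
            wPeer = 4.18, wSoc = 4.15, alphaPeerMix = 0.5,
            gammaOpen = 0.3, thetaCC = 0, thetaEC = 0,
            crossover = 0, crossoverOpenness = TRUE, crossoverUtility = TRUE,
            crossoverBidirectional = FALSE,
            kappaDual = 0, tasteScale = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown utility parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(dots)] <- dots
  validate_parameters(structure(p, class = "utility_params"))
}

#' @rdname default_parameters
#' @param p a `utility_params` list to validate.
#' @export
validate_parameters <- function(p) {
  num <- c("muCC", "muEC", "eta", "phi", "wPeer", "wSoc", "alphaPeerMix",
           "gammaOpen", "thetaCC", "thetaEC", "crossover", "kappaDual",
           "tasteScale")
  for (f in num)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]))
      stop(sprintf("parameter %s must be a single finite number", f),
           call. = FALSE)
  if (p$alphaPeerMix < 0 || p$alphaPeerMix > 1)
    stop("alphaPeerMix must lie in [0, 1]", call. = FALSE)
  if (p$kappaDual < 0) stop("kappaDual must be >= 0", call. = FALSE)
  if (p$tasteScale < 0) stop("tasteScale must be >= 0", call. = FALSE)
  for (f in c("thetaCC", "thetaEC", "crossover"))
    if (p[[f]] < 0 || p[[f]] > 0.3)
      warning(sprintf("%s = %g lies outside the scenario range [0, 0.3]",
                      f, p[[f]]), call. = FALSE)
  p
}

#' Read / write utility parameters as YAML
#'
#' @param path YAML file with a flat block of parameter fields.
#' @return [read_parameters()]: a validated `utility_params` list;
#'   [write_parameters()]: `path`, invisibly.
#' @export
read_parameters <- function(path) {
  do.call(default_parameters, yaml::read_yaml(path))
}

#' @rdname read_parameters
#' @param p a `utility_params` list.
#' @export
write_parameters <- function(p, path) {
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Close-peer prevalence seen by one agent
#'
#' Fraction of an agent's designated close friends (at most four) who
#' currently use each product; both zero for an agent with no close friends.
#'
#' @param agentId 0-based agent id.
#' @param net a `social_network` with close friends assigned.
#' @param states character vector of smoking states indexed by `agentId + 1`.
#' @return Named numeric vector `c(peerCC, peerEC)`.
#' @export
peer_prevalence <- function(agentId, net, states) {
  if (agentId < 0 || agentId >= net$n)
    stop("unknown agentId: ", agentId, call. = FALSE)
  friends <- net$closeFriends[agentId + 1L, ]
  friends <- friends[!is.na(friends)]
  if (length(friends) == 0L) return(c(peerCC = 0, peerEC = 0))
  st <- states[friends + 1L]
  c(peerCC = mean(uses_cc(st)), peerEC = mean(uses_ec(st)))
}

#' Population prevalence by product and state fractions
#'
#' @param states non-empty character vector of smoking states.
#' @return List with `popCC`, `popEC` (dual users counted in both) and
#'   `stateFractions`, a named vector over [SMOKING_STATES] summing to 1.
#' @export
population_prevalence <- function(states) {
  if (length(states) == 0L) stop("states must be non-empty", call. = FALSE)
  fr <- as.vector(table(factor(states, levels = SMOKING_STATES))) / length(states)
  names(fr) <- SMOKING_STATES
  list(popCC = mean(uses_cc(states)), popEC = mean(uses_ec(states)),
       stateFractions = fr)
}

#' Dynamic openness to each product
#'
#' Perceived exposure blends peer and population prevalence,
#' `E_X = alphaPeerMix * peer_X + (1 - alphaPeerMix) * pop_X`. Openness is
#' the agent's base attitude shifted by the scenario offset, the exposure
#' response, and — for cigarettes only — the one-way crossover from
#' e-cigarette exposure, clamped to \[0, 1\]:
#' \deqn{o_{EC} = clamp(b_{EC} + \theta_{EC} + \gamma E_{EC})}
#' \deqn{o_{CC} = clamp(b_{CC} + \theta_{CC} + \gamma E_{CC} + \chi E_{EC})}
#'
#' All arguments are vectorised over agents.
#'
#' @param baseOpennessCC,baseOpennessEC base openness in \[0, 1\].
#' @param peerCC,peerEC,popCC,popEC social signals in \[0, 1\].
#' @param params a `utility_params` list.
#' @return List with numeric vectors `oCC`, `oEC`, both in \[0, 1\].
#' @export
dynamic_openness <- function(baseOpennessCC, baseOpennessEC,
                             peerCC, peerEC, popCC, popEC, params) {
  a <- params$alphaPeerMix
  E_CC <- a * peerCC + (1 - a) * popCC
  E_EC <- a * peerEC + (1 - a) * popEC
  chiOpen <- if (isTRUE(params$crossoverOpenness)) params$crossover else 0
  chiBack <- if (isTRUE(params$crossoverBidirectional)) chiOpen else 0
  list(oCC = clamp01(baseOpennessCC + params$thetaCC +
                       params$gammaOpen * E_CC + chiOpen * E_EC),
       oEC = clamp01(baseOpennessEC + params$thetaEC +
                       params$gammaOpen * E_EC + chiBack * E_CC))
}

#' Utilities of the four smoking alternatives
#'
#' Non-use is the reference alternative, `U(NONE) = 0`. For each product
#' the component utility is
#' \deqn{V_X = \mu_X + \eta 1[uses X now] + \phi f_X +
#'   (w_{peer} peer_X + w_{soc} pop_X)(1 + o_X)}
#' with, for cigarettes, the additional direct crossover term
#' \eqn{\chi (w_{peer} peer_{EC} + w_{soc} pop_{EC})}. Then
#' `U(CC_ONLY) = V_CC`, `U(EC_ONLY) = V_EC` and
#' `U(DUAL) = V_CC + V_EC - kappaDual`.
#'
#' All agent-level arguments are vectorised.
#'
#' @param state current smoking state(s).
#' @param freqCC,freqEC current 30-day use frequencies in \[0, 1\].
#' @param oCC,oEC dynamic openness from [dynamic_openness()].
#' @param peerCC,peerEC,popCC,popEC social signals.
#' @param params a `utility_params` list.
#' @return Numeric matrix, one row per agent, columns
#'   `NONE, CC_ONLY, EC_ONLY, DUAL`.
#' @export
alternative_utilities <- function(state, freqCC, freqEC, oCC, oEC,
                                  peerCC, peerEC, popCC, popEC, params) {
  socCC <- params$wPeer * peerCC + params$wSoc * popCC
  socEC <- params$wPeer * peerEC + params$wSoc * popEC
  chiU <- if (isTRUE(params$crossoverUtility)) params$crossover else 0
  chiBack <- if (isTRUE(params$crossoverBidirectional)) chiU else 0
  vCC <- params$muCC + params$eta * uses_cc(state) + params$phi * freqCC +
    socCC * (1 + oCC) + chiU * socEC
  vEC <- params$muEC + params$eta * uses_ec(state) + params$phi * freqEC +
    socEC * (1 + oEC) + chiBack * socCC
  u <- cbind(NONE = rep(0, length(vCC)), CC_ONLY = vCC, EC_ONLY = vEC,
             DUAL = vCC + vEC - params$kappaDual)
  u
}

# vectorised choice over a utility matrix; consumes the ambient RNG stream
choose_states_matrix <- function(u, tasteScale) {
  if (any(!is.finite(u))) stop("non-finite utility", call. = FALSE)
  if (tasteScale > 0) {
    shock <- -log(-log(matrix(stats::runif(length(u)), nrow(u), ncol(u))))
    u <- u + tasteScale * shock
  }
  # ties broken by canonical state order NONE < CC_ONLY < EC_ONLY < DUAL
  SMOKING_STATES[max.col(u, ties.method = "first")]
}

#' Choose the next smoking state
#'
#' Adds an i.i.d. standard Gumbel shock, scaled by `tasteScale`, to each
#' alternative's utility and returns the argmax — the random-utility
#' formulation whose choice probabilities are the multinomial logit
#' `softmax(U / tasteScale)`. With `tasteScale = 0` the choice is the
#' deterministic argmax, ties broken in the fixed order
#' `NONE < CC_ONLY < EC_ONLY < DUAL`.
#'
#' @param utilities numeric vector of 4 finite utilities (order
#'   [SMOKING_STATES]), or a 4-column matrix of one row per agent.
#' @param tasteScale Gumbel scale, `>= 0`.
#' @return Chosen state name(s).
#' @examples
#' set.seed(1)
#' choose_state(c(0, 1, 0, 0.5), tasteScale = 1)
#' @export
choose_state <- function(utilities, tasteScale = 1) {
  if (is.null(dim(utilities))) utilities <- matrix(utilities, nrow = 1L)
  if (ncol(utilities) != 4L) stop("need 4 alternatives", call. = FALSE)
  choose_states_matrix(utilities, tasteScale)
}
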