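# Decision-cycle engine: synchronous updating, seeded replicates,
# scenario aggregation.

#' Scenario specification
#'
#' Bundles everything one simulation scenario needs: population size and
#' marginals, network attachment parameter, time axis, scenario knobs
#' (openness offsets and crossover), utility parameters, replicate count and
#' base seed. One decision cycle represents the survey's 30-day "current
#' use" window, so `cyclesPerYear = 12` by default.
#'
#' @param nAgents number of agents.
#' @param attachmentM preferential-attachment edges per arriving node.
#' @param cyclesPerYear decision cycles per calendar year.
#' @param startYear,endYear simulated calendar span; the population is
#'   initialised at `startYear`.
#' @param thetaCC,thetaEC,crossover scenario values copied into `params`.
#' @param nReplicates independent seeded replicates to average.
#' @param baseSeed integer; replicate `r` derives its seeds from
#'   `baseSeed + r`.
#' @param params a `utility_params` list.
#' @param marginals a `population_marginals` list.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(nAgents = 3000, attachmentM = 3, cyclesPerYear = 12,
                          startYear = 2011, endYear = 2014,
                          thetaCC = 0, thetaEC = 0, crossover = 0,
                          nReplicates = 100, baseSeed = 1,
                          params = default_parameters(),
                          marginals = default_marginals()) {
  if (endYear < startYear)
    stop("endYear must not precede startYear", call. = FALSE)
  if (nReplicates < 1) stop("nReplicates must be >= 1", call. = FALSE)
  params$thetaCC <- thetaCC
  params$thetaEC <- thetaEC
  params$crossover <- crossover
  validate_parameters(params)
  structure(list(nAgents = as.integer(nAgents),
                 attachmentM = as.integer(attachmentM),
                 cyclesPerYear = as.integer(cyclesPerYear),
                 startYear = as.integer(startYear),
                 endYear = as.integer(endYear),
                 nReplicates = as.integer(nReplicates),
                 baseSeed = as.integer(baseSeed),
                 params = params, marginals = marginals),
            class = "scenario_spec")
}

# deterministic sub-seed derivation: one scenario seed fans out to
# population / network / close-friend / cycle streams (kept below 2^31)
derive_seed <- function(base, stream) {
  as.integer((as.numeric(base) * 48271 + stream * 16807) %% 2147483647)
}

#' Advance the population one decision cycle
#'
#' Synchronous update: peer and population prevalences are computed from the
#' pre-step states, every agent's dynamic openness and alternative utilities
#' are evaluated against that common lagged environment, and all agents draw
#' their next state at once (agents in `agentId` order, one Gumbel shock per
#' agent-alternative from the ambient RNG stream). Use frequencies then
#' ramp: `freq_X <- min(1, freq_X + 0.25)` while the product is used, else
#' reset to 0.
#'
#' @param sim simulation state: list with `state`, `freqCC`, `freqEC`,
#'   `baseOpennessCC`, `baseOpennessEC`, and precomputed close-friend index
#'   matrix `cfIndex` (1-based, `NA`-padded).
#' @param params a `utility_params` list.
#' @return The updated simulation state.
#' @export
step_cycle <- function(sim, params) {
  state <- sim$state
  usesCCv <- uses_cc(state)
  usesECv <- uses_ec(state)
  popCC <- mean(usesCCv)
  popEC <- mean(usesECv)

  cf <- sim$cfIndex
  nFriends <- sim$nCloseFriends
  peerCC <- rowSums(matrix(usesCCv[cf], nrow(cf), ncol(cf)), na.rm = TRUE) / nFriends
  peerEC <- rowSums(matrix(usesECv[cf], nrow(cf), ncol(cf)), na.rm = TRUE) / nFriends
  peerCC[nFriends == 0L] <- 0
  peerEC[nFriends == 0L] <- 0

  op <- dynamic_openness(sim$baseOpennessCC, sim$baseOpennessEC,
                         peerCC, peerEC, popCC, popEC, params)
  u <- alternative_utilities(state, sim$freqCC, sim$freqEC, op$oCC, op$oEC,
                             peerCC, peerEC, popCC, popEC, params)
  newState <- choose_states_matrix(u, params$tasteScale)

  sim$state <- newState
  sim$freqCC <- ifelse(uses_cc(newState), pmin(1, sim$freqCC + 0.25), 0)
  sim$freqEC <- ifelse(uses_ec(newState), pmin(1, sim$freqEC + 0.25), 0)
  sim
}

# package profiles + network into the flat simulation state used by the loop
init_sim_state <- function(profiles, net) {
  profiles <- profiles[order(profiles$agentId), ]
  cf <- net$closeFriends + 1L
  list(state = profiles$state,
       freqCC = profiles$freqCC,
       freqEC = profiles$freqEC,
       baseOpennessCC = profiles$baseOpennessCC,
       baseOpennessEC = profiles$baseOpennessEC,
       cfIndex = cf,
       nCloseFriends = rowSums(!is.na(cf)))
}

#' Run one seeded replicate
#'
#' Builds a fresh population and network from seeds derived from
#' `baseSeed + replicateId`, then advances
#' `cyclesPerYear * (endYear - startYear)` decision cycles, recording the
#' state-fraction 4-vector after every cycle and at each survey anniversary
#' (including the initialisation).
#'
#' @param spec a `scenario_spec`.
#' @param replicateId non-negative integer.
#' @param profiles,net optional pre-built population and network (used by
#'   callers that hold them fixed); by default both are rebuilt per replicate.
#' @return A `trajectory_result` list: `perCycle` (`(nCycles+1) x 4` matrix,
#'   row 1 = initial state), `perYear` (one row per calendar year),
#'   `years`, `replicateId`.
#' @export
run_replicate <- function(spec, replicateId = 0L, profiles = NULL, net = NULL) {
  rseed <- spec$baseSeed + as.integer(replicateId)
  if (is.null(profiles))
    profiles <- generate_profiles(spec$nAgents, spec$marginals,
                                  seed = derive_seed(rseed, 1L))
  if (is.null(net)) {
    net <- build_scale_free(spec$nAgents, spec$attachmentM,
                            seed = derive_seed(rseed, 2L))
    net <- assign_close_friends(net, profiles, seed = derive_seed(rseed, 3L))
  }
  sim <- init_sim_state(profiles, net)

  nYears <- spec$endYear - spec$startYear
  nCycles <- spec$cyclesPerYear * nYears
  perCycle <- matrix(NA_real_, nCycles + 1L, 4L,
                     dimnames = list(NULL, SMOKING_STATES))
  perCycle[1L, ] <- population_prevalence(sim$state)$stateFractions

  set.seed(derive_seed(rseed, 4L))
  for (t in seq_len(nCycles)) {
    sim <- step_cycle(sim, spec$params)
    perCycle[t + 1L, ] <- population_prevalence(sim$state)$stateFractions
  }
  anniversaries <- 1L + spec$cyclesPerYear * (0:nYears)
  structure(list(perCycle = perCycle,
                 perYear = perCycle[anniversaries, , drop = FALSE],
                 years = spec$startYear:spec$endYear,
                 replicateId = as.integer(replicateId)),
            class = "trajectory_result")
}

#' Run a scenario: replicate ensemble and aggregate
#'
#' Runs `nReplicates` independent replicates (seeds `baseSeed + 0 ..
#' baseSeed + nReplicates - 1`) and aggregates the per-cycle and per-year
#' state fractions into means and standard deviations across replicates.
#'
#' @param spec a `scenario_spec`.
#' @return A `scenario_result` list with `perCycleMean`, `perCycleSD`,
#'   `perYearMean`, `perYearSD` (matrices, columns [SMOKING_STATES]),
#'   `years`, `nReplicates`, and the `spec`.
#' @examples
#' spec <- scenario_spec(nAgents = 200, nReplicates = 2, baseSeed = 5)
#' res <- run_scenario(spec)
#' res$perYearMean
#' @export
run_scenario <- function(spec) {
  reps <- lapply(seq_len(spec$nReplicates) - 1L,
                 function(r) run_replicate(spec, r))
  agg <- function(field) {
    arr <- vapply(reps, function(x) x[[field]],
                  matrix(0, nrow(reps[[1L]][[field]]), 4L))
    list(mean = apply(arr, c(1, 2), mean),
         sd = if (length(reps) > 1L) apply(arr, c(1, 2), stats::sd)
              else matrix(0, nrow(arr), 4L))
  }
  pc <- agg("perCycle")
  py <- agg("perYear")
  dimnames(pc$mean) <- dimnames(pc$sd) <- list(NULL, SMOKING_STATES)
  dimnames(py$mean) <- dimnames(py$sd) <-
    list(reps[[1L]]$years, SMOKING_STATES)
  structure(list(perCycleMean = pc$mean, perCycleSD = pc$sd,
                 perYearMean = py$mean, perYearSD = py$sd,
                 years = reps[[1L]]$years,
                 nReplicates = spec$nReplicates, spec = spec),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %d agents, %d replicates, %d-%d\n",
              x$spec$nAgents, x$nReplicates, x$spec$startYear, x$spec$endYear))
  cat(sprintf("theta = (%.2f, %.2f), crossover = %.2f\n",
              x$spec$params$thetaCC, x$spec$params$thetaEC,
              x$spec$params$crossover))
  cat("Mean state fractions at survey anniversaries (%):\n")
  print(round(100 * x$perYearMean, 2))
  invisible(x)
}

#' Product-level prevalence from state fractions
#'
#' @param fractions matrix or vector of state fractions (columns/names
#'   [SMOKING_STATES]).
#' @return Matrix (or vector) with columns `popCC`, `popEC`; dual users
#'   count in both.
#' @export
product_prevalence <- function(fractions) {
  if (is.null(dim(fractions))) fractions <- rbind(fractions)
  cbind(popCC = fractions[, "CC_ONLY"] + fractions[, "DUAL"],
        popEC = fractions[, "EC_ONLY"] + fractions[, "DUAL"])
}

#' Write a scenario result as tidy CSV
#'
#' One row per replicate-cycle plus `mean` and `sd` aggregate rows, columns
#' `scenarioId, replicateId, year, cycle, fracNone, fracCCOnly, fracECOnly,
#' fracDual, popCC, popEC`. To keep files small only aggregate rows are
#' written unless per-replicate trajectories are supplied.
#'
#' @param result a `scenario_result`.
#' @param path output CSV path.
#' @param scenarioId identifier written in the first column.
#' @param replicates optional list of `trajectory_result`s to include.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(result, path, scenarioId = "scenario",
                               replicates = NULL) {
  spec <- result$spec
  cycles <- 0:(nrow(result$perCycleMean) - 1L)
  yearOf <- spec$startYear + cycles %/% spec$cyclesPerYear
  row_block <- function(mat, label) {
    pp <- product_prevalence(mat)
    data.frame(scenarioId = scenarioId, replicateId = label,
               year = yearOf, cycle = cycles,
               fracNone = mat[, "NONE"], fracCCOnly = mat[, "CC_ONLY"],
               fracECOnly = mat[, "EC_ONLY"], fracDual = mat[, "DUAL"],
               popCC = pp[, "popCC"], popEC = pp[, "popEC"])
  }
  out <- do.call(rbind, c(
    lapply(replicates, function(r) row_block(r$perCycle, r$replicateId)),
    list(row_block(result$perCycleMean, "mean"),
         row_block(result$perCycleSD, "sd"))))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
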