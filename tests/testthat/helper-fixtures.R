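# Small fixtures shared across test files.

# marginals with no user/non-user correlation (the spec's independent case)
independent_marginals <- function(stateProbs = c(NONE = 0.8, CC_ONLY = 0.1,
                                                 EC_ONLY = 0.05, DUAL = 0.05),
                                  friendCountProbs = c(0.65, 0.17, 0.09,
                                                       0.05, 0.04)) {
  default_marginals(stateProbs = stateProbs,
                    friendCountProbs = friendCountProbs,
                    friendCountProbsUser = friendCountProbs,
                    opennessItemProbs = c(0.64, 0.22, 0.10, 0.04),
                    opennessItemProbsUser = c(0.64, 0.22, 0.10, 0.04))
}

# a fast, small scenario for engine-level tests
tiny_spec <- function(...) {
  args <- utils::modifyList(list(nAgents = 200, attachmentM = 2,
                                 nReplicates = 2, baseSeed = 7),
                            list(...))
  do.call(scenario_spec, args)
}

# exact two-sided binomial CI bounds for an empirical proportion
binom_ci <- function(n, p, level = 0.99) {
  a <- (1 - level) / 2
  c(lower = stats::qbinom(a, n, p) / n,
    upper = stats::qbinom(1 - a, n, p) / n)
}
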