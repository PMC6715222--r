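make_net_with_friends <- function(states, friends) {
  # one focal agent (id 0) with the given close friends holding `states`
  n <- length(states) + 1L
  structure(list(n = n,
                 edges = cbind(from = rep(0L, n - 1L), to = seq_len(n - 1L)),
                 closeFriends = rbind(c(friends, rep(NA_integer_, 4 - length(friends))),
                                      matrix(NA_integer_, n - 1L, 4L)),
                 discrepancy = rep(0L, n)),
            class = "social_network")
}

test_that("peer prevalence counts dual users in both products", {
  st <- c("DUAL", "DUAL", "EC_ONLY", "NONE")
  net <- make_net_with_friends(st, 1:4)
  states <- c("NONE", st)
  expect_equal(peer_prevalence(0, net, states),
               c(peerCC = 0.5, peerEC = 0.75))

  netCC <- make_net_with_friends(rep("CC_ONLY", 4), 1:4)
  expect_equal(peer_prevalence(0, netCC, c("NONE", rep("CC_ONLY", 4))),
               c(peerCC = 1, peerEC = 0))

  # isolated agent: defined as zero
  iso <- make_net_with_friends("NONE", integer(0))
  expect_equal(peer_prevalence(0, iso, c("NONE", "NONE")),
               c(peerCC = 0, peerEC = 0))
  expect_error(peer_prevalence(99, iso, c("NONE", "NONE")), "unknown agentId")
})

test_that("population prevalence and state fractions are exact", {
  st <- c(rep("NONE", 6), "CC_ONLY", rep("EC_ONLY", 2), "DUAL")
  pp <- population_prevalence(st)
  expect_equal(pp$popCC, 0.2)
  expect_equal(pp$popEC, 0.3)
  expect_equal(unname(pp$stateFractions), c(0.6, 0.1, 0.2, 0.1))

  allNone <- population_prevalence(rep("NONE", 10))
  expect_equal(allNone$popCC, 0)
  expect_equal(unname(allNone$stateFractions), c(1, 0, 0, 0))
  expect_error(population_prevalence(character(0)), "non-empty")

  set.seed(1)
  for (i in 1:20) {
    st <- sample(SMOKING_STATES, 57, replace = TRUE)
    expect_equal(sum(population_prevalence(st)$stateFractions), 1)
  }
})

test_that("dynamic openness reduces to base openness at zero exposure", {
  p <- default_parameters()
  op <- dynamic_openness(0.3, 0.7, 0, 0, 0, 0, p)
  expect_equal(op$oCC, 0.3)
  expect_equal(op$oEC, 0.7)
})

test_that("dynamic openness clamps to [0, 1]", {
  p <- default_parameters(thetaCC = 0.3, gammaOpen = 2)
  op <- dynamic_openness(0.9, 0.9, 0.5, 0.5, 0.5, 0.5, p)
  expect_equal(op$oCC, 1)
  set.seed(2)
  for (i in 1:50) {
    p2 <- default_parameters(gammaOpen = runif(1, 0, 3),
                             crossover = runif(1, 0, 0.3))
    op <- dynamic_openness(runif(1), runif(1), runif(1), runif(1),
                           runif(1), runif(1), p2)
    expect_true(op$oCC >= 0 && op$oCC <= 1 && op$oEC >= 0 && op$oEC <= 1)
  }
})

test_that("dynamic openness matches the hand-computed crossover example", {
  p <- default_parameters(alphaPeerMix = 0.5, gammaOpen = 0.5,
                          crossover = 0.3, thetaCC = 0, thetaEC = 0)
  op <- dynamic_openness(0.2, 0.2, peerCC = 0, peerEC = 0.4,
                         popCC = 0, popEC = 0.2, p)
  # E_EC = 0.3; oCC = 0.2 + 0.3*0.3; oEC = 0.2 + 0.5*0.3
  expect_equal(op$oCC, 0.29)
  expect_equal(op$oEC, 0.35)
})

test_that("alternative utilities match hand-computed cases", {
  null <- default_parameters(muCC = 0, muEC = 0, eta = 0, phi = 0, wPeer = 0,
                             wSoc = 0, gammaOpen = 0, kappaDual = 0)
  u <- alternative_utilities("NONE", 0, 0, 0.5, 0.5, 0, 0, 0, 0, null)
  expect_equal(as.vector(u), c(0, 0, 0, 0))

  onlyMu <- default_parameters(muCC = 1, muEC = 0, eta = 0, phi = 0,
                               wPeer = 0, wSoc = 0, gammaOpen = 0,
                               kappaDual = 0.5)
  u <- alternative_utilities("NONE", 0, 0, 0, 0, 0, 0, 0, 0, onlyMu)
  expect_equal(as.vector(u), c(0, 1, 0, 0.5))

  # full worked example incl. habituation and the direct crossover channel
  p <- default_parameters(muCC = -1, muEC = -0.5, eta = 0.8, phi = 0,
                          wPeer = 2, wSoc = 1, crossover = 0.3,
                          kappaDual = 0.5)
  u <- alternative_utilities("EC_ONLY", freqCC = 0, freqEC = 1,
                             oCC = 0.29, oEC = 0.35,
                             peerCC = 0, peerEC = 0.4, popCC = 0, popEC = 0.2,
                             p)
  expect_equal(as.vector(u), c(0, -0.7, 1.65, 0.45), tolerance = 1e-12)
})

test_that("the bidirectional switch mirrors the coupling onto the EC side", {
  p <- default_parameters(crossover = 0.3, gammaOpen = 0, wPeer = 2, wSoc = 1)
  p2 <- default_parameters(crossover = 0.3, gammaOpen = 0, wPeer = 2,
                           wSoc = 1, crossoverBidirectional = TRUE)
  op1 <- dynamic_openness(0.2, 0.2, 0.4, 0, 0.2, 0, p)
  op2 <- dynamic_openness(0.2, 0.2, 0.4, 0, 0.2, 0, p2)
  expect_equal(op1$oEC, 0.2)                 # one-way: EC side untouched
  expect_equal(op2$oEC, 0.2 + 0.3 * 0.3)     # mirrored: E_CC = 0.3
  u1 <- alternative_utilities("NONE", 0, 0, 0.2, 0.2, 0.4, 0, 0.2, 0, p)
  u2 <- alternative_utilities("NONE", 0, 0, 0.2, 0.2, 0.4, 0, 0.2, 0, p2)
  expect_equal(u1[, "CC_ONLY"], u2[, "CC_ONLY"])
  expect_equal(u2[, "EC_ONLY"] - u1[, "EC_ONLY"], c(0.3 * (2 * 0.4 + 1 * 0.2)),
               ignore_attr = TRUE)
})

test_that("with zero crossover and openness response, products are independent", {
  p <- default_parameters(crossover = 0, gammaOpen = 0)
  u1 <- alternative_utilities("NONE", 0, 0, 0.2, 0.2, 0.1, 0.0, 0.1, 0.0, p)
  u2 <- alternative_utilities("NONE", 0, 0, 0.2, 0.2, 0.1, 0.9, 0.1, 0.9, p)
  expect_equal(u1[, "CC_ONLY"], u2[, "CC_ONLY"])
  op1 <- dynamic_openness(0.2, 0.2, 0.1, 0.0, 0.1, 0.0, p)
  op2 <- dynamic_openness(0.2, 0.2, 0.1, 0.9, 0.1, 0.9, p)
  expect_equal(op1$oCC, op2$oCC)
})

test_that("deterministic choice takes the argmax with fixed tie order", {
  expect_equal(choose_state(c(0.2, 0.2, 0.1, 0.0), tasteScale = 0), "NONE")
  expect_equal(choose_state(c(-1, 3, 2, 3), tasteScale = 0), "CC_ONLY")
  expect_error(choose_state(c(0, NA, 0, 0), 1), "non-finite")
})

test_that("Gumbel-shock choice frequencies match the closed-form logit", {
  # symmetric case
  set.seed(5)
  picks <- choose_state(matrix(0, 4e4, 4), tasteScale = 1)
  freq <- table(factor(picks, SMOKING_STATES)) / 4e4
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 4e4)))

  # one raised utility: P(NONE) = e / (e + 3)
  set.seed(6)
  u <- matrix(rep(c(1, 0, 0, 0), each = 1e6), ncol = 4)
  picks <- choose_state(u, tasteScale = 1)
  pNone <- exp(1) / (exp(1) + 3)
  se <- sqrt(pNone * (1 - pNone) / 1e6)
  expect_lt(abs(mean(picks == "NONE") - pNone), 3 * se)

  # general softmax oracle at a random utility vector and scale
  set.seed(7)
  uv <- c(0.3, -0.4, 1.1, 0.2)
  tau <- 0.7
  probs <- exp(uv / tau) / sum(exp(uv / tau))
  picks <- choose_state(matrix(rep(uv, each = 1e5), ncol = 4), tasteScale = tau)
  freq <- as.vector(table(factor(picks, SMOKING_STATES))) / 1e5
  expect_true(all(abs(freq - probs) < 3 * sqrt(probs * (1 - probs) / 1e5)))
})

test_that("raising one alternative's utility weakly raises its choice rate", {
  set.seed(8)
  base <- c(0, 0.5, 0.2, -0.3)
  for (delta in c(0.5, 1.5)) {
    lifted <- base; lifted[3] <- lifted[3] + delta
    p0 <- mean(choose_state(matrix(rep(base, each = 3e4), ncol = 4), 1) ==
                 "EC_ONLY")
    p1 <- mean(choose_state(matrix(rep(lifted, each = 3e4), ncol = 4), 1) ==
                 "EC_ONLY")
    expect_gt(p1, p0)
  }
})

test_that("parameter validation flags impossible values and scenario ranges", {
  expect_error(default_parameters(alphaPeerMix = 1.5), "alphaPeerMix")
  expect_error(default_parameters(kappaDual = -1), "kappaDual")
  expect_error(default_parameters(tasteScale = -0.1), "tasteScale")
  expect_error(default_parameters(bogus = 1), "unknown")
  expect_warning(default_parameters(crossover = 0.5), "outside the scenario range")
  path <- withr::local_tempfile(fileext = ".yaml")
  p <- default_parameters(muCC = -3.21, crossover = 0.2)
  write_parameters(p, path)
  expect_equal(read_parameters(path), p)
})
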