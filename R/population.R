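# Agent states and synthetic initial populations.

#' Smoking states
#'
#' Agents occupy exactly one of four mutually exclusive 30-day "current use"
#' states: `NONE` (non-user), `CC_ONLY` (conventional cigarettes only),
#' `EC_ONLY` (e-cigarettes only) and `DUAL` (both products).
#'
#' @format Character vector of the four state names, in canonical order.
#' @export
SMOKING_STATES <- c("NONE", "CC_ONLY", "EC_ONLY", "DUAL")

#' Product-use indicators
#'
#' A `DUAL` user counts as a current user of both products, matching the
#' survey convention that product-level prevalence includes dual users.
#'
#' @param state character vector of smoking states (see [SMOKING_STATES]).
#' @return Logical vector: does the state involve current use of the product?
#' @examples
#' uses_cc(c("NONE", "CC_ONLY", "EC_ONLY", "DUAL"))
#' @export
uses_cc <- function(state) state %in% c("CC_ONLY", "DUAL")

#' @rdname uses_cc
#' @export
uses_ec <- function(state) state %in% c("EC_ONLY", "DUAL")

# scoring of the two 4-point openness survey items
# ("definitely not" ... "definitely yes") onto [0, 1]
OPENNESS_ITEM_SCORES <- c(0, 1 / 3, 2 / 3, 1)

#' Default population marginals
#'
#' Marginal distributions used to generate synthetic agent profiles that
#' emulate the 2011 US National Youth Tobacco Survey high-school profile:
#' the 30-day smoking-state distribution, the distribution of "how many of
#' your four closest friends smoke cigarettes?", the response distribution
#' of the two 4-point openness items ("If one of your friends offered you a
#' cigarette, would you smoke it?", "Do you think you will smoke a cigarette
#' anytime during the next year?"), the age range, and the 30-day use
#' frequency of current users.
#'
#' The packaged defaults put 2011 cigarette prevalence (including dual use)
#' at 15.8% and e-cigarette prevalence at 1.5%. All components can be
#' overridden, either here or via a YAML file ([read_marginals()]).
#'
#' @param stateProbs named probability vector over [SMOKING_STATES].
#' @param friendCountProbs probability vector over 0..4 smoking close
#'   friends, for agents who currently use neither product.
#' @param friendCountProbsUser probability vector over 0..4 smoking close
#'   friends for current users of either product. Smoking clusters in
#'   friendship networks, and the survey item reflects that: current
#'   smokers report far more smoking friends. Set equal to
#'   `friendCountProbs` for an independent population.
#' @param opennessItemProbs probability vector over the 4 item responses
#'   (least to most open) for agents who currently use neither product;
#'   used for both items and both products unless `opennessItemProbsEC`
#'   is supplied.
#' @param opennessItemProbsUser item response distribution for current
#'   users of either product. Openness is drawn conditional on smoking
#'   state because the survey items (offered-a-cigarette, smoke-next-year)
#'   are answered affirmatively by most current smokers; an
#'   openness-state-independent population cannot reproduce observed
#'   dual-use levels. Set equal to `opennessItemProbs` for a fully
#'   independent population.
#' @param opennessItemProbsEC optional separate item distribution for
#'   e-cigarette openness of non-users; defaults to `opennessItemProbs`
#'   (the survey items are cigarette-phrased).
#' @param ageRange integer range of ages (years) sampled uniformly.
#' @param freqShape1,freqShape2 Beta parameters of initial 30-day use
#'   frequency (fraction of days) for current users of a product.
#' @return A list of class `population_marginals`.
#' @export
default_marginals <- function(stateProbs = c(NONE = 0.839, CC_ONLY = 0.146,
                                             EC_ONLY = 0.003, DUAL = 0.012),
                              friendCountProbs = c(0.72, 0.15, 0.07, 0.04, 0.02),
                              friendCountProbsUser = c(0.10, 0.20, 0.30, 0.20, 0.20),
                              opennessItemProbs = c(0.697, 0.277, 0.024, 0.002),
                              opennessItemProbsUser = c(0.004, 0.006, 0.007, 0.983),
                              opennessItemProbsEC = opennessItemProbs,
                              ageRange = c(14L, 18L),
                              freqShape1 = 3, freqShape2 = 1.3) {
  m <- structure(list(stateProbs = stateProbs,
                      friendCountProbs = friendCountProbs,
                      friendCountProbsUser = friendCountProbsUser,
                      opennessItemProbs = opennessItemProbs,
                      opennessItemProbsUser = opennessItemProbsUser,
                      opennessItemProbsEC = opennessItemProbsEC,
                      ageRange = as.integer(ageRange),
                      freqShape1 = freqShape1, freqShape2 = freqShape2),
                 class = "population_marginals")
  validate_marginals(m)
  m
}

#' Validate population marginals
#'
#' Checks that every probability vector is non-negative, sums to 1 within
#' 1e-9, and has the right length; errors name the offending field.
#'
#' @param m a `population_marginals` list.
#' @return `m`, invisibly.
#' @export
validate_marginals <- function(m) {
  check_probs <- function(p, field, len) {
    if (length(p) != len)
      stop(sprintf("marginals$%s must have length %d", field, len), call. = FALSE)
    if (any(!is.finite(p)) || any(p < 0))
      stop(sprintf("marginals$%s has negative or non-finite entries", field),
           call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9)
      stop(sprintf("marginals$%s does not sum to 1 (sum = %.12g)", field, sum(p)),
           call. = FALSE)
  }
  check_probs(m$stateProbs, "stateProbs", 4L)
  check_probs(m$friendCountProbs, "friendCountProbs", 5L)
  check_probs(m$friendCountProbsUser, "friendCountProbsUser", 5L)
  check_probs(m$opennessItemProbs, "opennessItemProbs", 4L)
  check_probs(m$opennessItemProbsUser, "opennessItemProbsUser", 4L)
  check_probs(m$opennessItemProbsEC, "opennessItemProbsEC", 4L)
  if (length(m$ageRange) != 2L || m$ageRange[1] > m$ageRange[2] ||
      m$ageRange[1] < 13L || m$ageRange[2] > 19L)
    stop("marginals$ageRange must be an increasing pair within [13, 19]",
         call. = FALSE)
  if (m$freqShape1 <= 0 || m$freqShape2 <= 0)
    stop("marginals$freqShape1/freqShape2 must be positive", call. = FALSE)
  invisible(m)
}

#' Read population marginals from a YAML file
#'
#' @param path YAML file with any subset of the [default_marginals()] fields;
#'   missing fields keep their defaults. `stateProbs` may be a named map.
#' @return A validated `population_marginals` list.
#' @export
read_marginals <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$stateProbs)) {
    sp <- unlist(raw$stateProbs)
    if (!is.null(names(sp)) && all(nzchar(names(sp)))) {
      missing <- setdiff(SMOKING_STATES, names(sp))
      if (length(missing))
        stop("marginals$stateProbs is missing states: ",
             paste(missing, collapse = ", "), call. = FALSE)
      sp <- sp[SMOKING_STATES]
    }
    args$stateProbs <- stats::setNames(as.numeric(sp), SMOKING_STATES)
  }
  for (f in c("friendCountProbs", "friendCountProbsUser",
              "opennessItemProbs", "opennessItemProbsUser",
              "opennessItemProbsEC", "ageRange", "freqShape1", "freqShape2"))
    if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  do.call(default_marginals, args)
}

# sample() without the length-1 "x is a count" surprise
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Generate a synthetic agent population
#'
#' Draws `n` agent profiles independently from the supplied marginals.
#' Base openness to each product is the mean of two independent survey-item
#' draws scored at equally spaced points 0, 1/3, 2/3, 1. Use frequencies are
#' drawn conditional on state: an agent's 30-day frequency for a product is
#' Beta-distributed if the agent currently uses that product and exactly 0
#' otherwise. Attributes are mutually independent across fields and agents.
#'
#' @param n number of agents (positive integer).
#' @param marginals a `population_marginals` list (see [default_marginals()]).
#' @param seed integer seed; identical `(n, marginals, seed)` give identical
#'   output.
#' @return A `data.frame` with one row per agent and columns `agentId`
#'   (0-based), `age`, `state`, `numSmokingFriends`, `baseOpennessCC`,
#'   `baseOpennessEC`, `freqCC`, `freqEC`.
#' @examples
#' pop <- generate_profiles(100, default_marginals(), seed = 1)
#' table(pop$state)
#' @export
generate_profiles <- function(n, marginals = default_marginals(), seed) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
    stop("n must be a positive integer", call. = FALSE)
  validate_marginals(marginals)
  n <- as.integer(n)
  set.seed(as.integer(seed))

  state <- resample(SMOKING_STATES, n, replace = TRUE, prob = marginals$stateProbs)
  age <- resample(seq(marginals$ageRange[1], marginals$ageRange[2]), n,
                  replace = TRUE)
  isUser <- state != "NONE"
  numSmokingFriends <- ifelse(
    isUser,
    resample(0:4, n, replace = TRUE, prob = marginals$friendCountProbsUser),
    resample(0:4, n, replace = TRUE, prob = marginals$friendCountProbs))
  draw_openness <- function(probsNonuser) {
    draw <- function(probs) {
      item1 <- resample(OPENNESS_ITEM_SCORES, n, replace = TRUE, prob = probs)
      item2 <- resample(OPENNESS_ITEM_SCORES, n, replace = TRUE, prob = probs)
      (item1 + item2) / 2
    }
    ifelse(isUser, draw(marginals$opennessItemProbsUser), draw(probsNonuser))
  }
  baseOpennessCC <- draw_openness(marginals$opennessItemProbs)
  baseOpennessEC <- draw_openness(marginals$opennessItemProbsEC)
  freqCC <- ifelse(uses_cc(state),
                   stats::rbeta(n, marginals$freqShape1, marginals$freqShape2), 0)
  freqEC <- ifelse(uses_ec(state),
                   stats::rbeta(n, marginals$freqShape1, marginals$freqShape2), 0)

  data.frame(agentId = 0:(n - 1L), age = age, state = state,
             numSmokingFriends = numSmokingFriends,
             baseOpennessCC = baseOpennessCC, baseOpennessEC = baseOpennessEC,
             freqCC = freqCC, freqEC = freqEC, stringsAsFactors = FALSE)
}

PROFILE_COLUMNS <- c("agentId", "age", "state", "numSmokingFriends",
                     "baseOpennessCC", "baseOpennessEC", "freqCC", "freqEC")

#' Write agent profiles to CSV
#'
#' @param profiles a profile `data.frame` as from [generate_profiles()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles[, PROFILE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load and validate agent profiles from CSV
#'
#' Enforces the profile schema: all columns present, states drawn from
#' [SMOKING_STATES], friend counts in 0..4, openness and frequencies in
#' \[0, 1\], frequencies positive only for users of the product, and unique
#' agent ids. Violations raise an error citing the offending row.
#'
#' @param path CSV written by [write_profiles()] (header plus one row per
#'   agent). A header-only file yields an empty, well-formed data frame.
#' @return A validated profile `data.frame`, row order preserved.
#' @export
load_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PROFILE_COLUMNS, names(df))
  if (length(missing))
    stop("profile file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[, PROFILE_COLUMNS]
  if (nrow(df) == 0L) return(df)

  fail_rows <- function(bad, what) {
    if (any(bad))
      stop(sprintf("invalid profile: %s on row %s", what,
                   paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  fail_rows(duplicated(df$agentId), "duplicate agentId")
  fail_rows(is.na(df$agentId) | df$agentId < 0, "negative or missing agentId")
  fail_rows(!(df$state %in% SMOKING_STATES), "unknown smoking state")
  fail_rows(is.na(df$numSmokingFriends) | !(df$numSmokingFriends %in% 0:4),
            "numSmokingFriends outside 0..4")
  fail_rows(is.na(df$age) | df$age < 13 | df$age > 19, "age outside [13, 19]")
  for (col in c("baseOpennessCC", "baseOpennessEC", "freqCC", "freqEC"))
    fail_rows(is.na(df[[col]]) | df[[col]] < 0 | df[[col]] > 1,
              sprintf("%s outside [0, 1]", col))
  fail_rows(df$freqCC > 0 & !uses_cc(df$state), "freqCC > 0 for a non-CC state")
  fail_rows(df$freqEC > 0 & !uses_ec(df$state), "freqEC > 0 for a non-EC state")
  df
}
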