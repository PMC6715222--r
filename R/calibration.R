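# Calibration to yearly prevalence targets, backward validation against
# 95% CIs, and the counterfactual openness x crossover grid.

#' Yearly prevalence calibration targets
#'
#' Reads targets from a CSV with columns `year, product (CC|EC), prev,
#' ciLow, ciHigh` (prevalences as fractions or percentages — percentages
#' are detected and divided by 100). The packaged default file carries the
#' US National Youth Tobacco Survey high-school current-use point estimates
#' and 95% confidence intervals for 2011-2014, the trend the model is
#' calibrated and backward-validated against; the 2015 survey is excluded
#' by design.
#'
#' @param path targets CSV; default: the packaged NYTS-derived file.
#' @return A `data.frame` with columns `year, product, prev, ciLow, ciHigh`
#'   (fractions).
#' @export
load_targets <- function(path = system.file("extdata", "nyts_targets.csv",
                                            package = "smokesim")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "product", "prev", "ciLow", "ciHigh")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("targets file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  if (any(!df$product %in% c("CC", "EC")))
    stop("targets product must be 'CC' or 'EC'", call. = FALSE)
  if (max(df$prev) > 1) {  # percentages
    df[c("prev", "ciLow", "ciHigh")] <- df[c("prev", "ciLow", "ciHigh")] / 100
  }
  bad <- df$ciLow > df$prev | df$prev > df$ciHigh
  if (any(bad))
    stop("target CI does not bracket the point estimate on row ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  df
}

# simulated product prevalence at each target (year, product)
simulated_at_targets <- function(result, targets) {
  idx <- match(targets$year, result$years)
  if (anyNA(idx))
    stop("targets contain years outside the simulated span: ",
         paste(unique(targets$year[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  pp <- product_prevalence(result$perYearMean)
  ifelse(targets$product == "CC", pp[idx, "popCC"], pp[idx, "popEC"])
}

#' Calibration loss
#'
#' Sum over targets of the squared deviation between simulated and observed
#' prevalence, normalised by the 95% CI half-width, so products measured
#' more precisely weigh more:
#' \deqn{L = \sum_{y,X} ((sim_{y,X} - obs_{y,X}) / halfCI_{y,X})^2}
#'
#' @param result a `scenario_result`.
#' @param targets targets data frame ([load_targets()]).
#' @return The scalar loss.
#' @export
calibration_loss <- function(result, targets) {
  sim <- simulated_at_targets(result, targets)
  halfCI <- (targets$ciHigh - targets$ciLow) / 2
  if (any(halfCI <= 0)) halfCI[halfCI <= 0] <- 1e-6
  sum(((sim - targets$prev) / halfCI)^2)
}

#' Calibrate free utility parameters to prevalence targets
#'
#' Searches a bounded box over the named free parameters, minimising
#' [calibration_loss()]. The search is Latin-hypercube seeding over 60% of
#' the evaluation budget followed by local refinement: Gaussian
#' perturbations of the incumbent with a radius that shrinks geometrically,
#' clipped to the bounds. Every evaluation simulates the scenario with
#' `nReplicatesSearch` replicates under common random numbers (the
#' template's `baseSeed`), so the objective is deterministic given `seed`
#' and the whole run is reproducible.
#'
#' @param spec a `scenario_spec` template; its `params` provide values for
#'   every non-free parameter.
#' @param freeParams character vector of `utility_params` field names to fit.
#' @param lower,upper numeric bounds, one per free parameter.
#' @param targets targets data frame ([load_targets()]).
#' @param budget total number of objective evaluations (>= 1).
#' @param nReplicatesSearch replicates per evaluation during the search.
#' @param seed integer seed for the search itself.
#' @return List of class `calibration_fit`: `params` (best full
#'   `utility_params`), `best` (named vector of fitted values), `loss`
#'   (best loss), `trace` (data.frame of all evaluations), `evaluations`.
#' @export
calibrate <- function(spec, freeParams = c("muCC", "muEC", "wPeer", "wSoc",
                                           "gammaOpen", "eta"),
                      lower, upper, targets = load_targets(),
                      budget = 200, nReplicatesSearch = 20, seed = 1) {
  if (nrow(targets) < 1L) stop("need at least one target", call. = FALSE)
  k <- length(freeParams)
  if (length(lower) != k || length(upper) != k)
    stop("lower/upper must match freeParams in length", call. = FALSE)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper))
    stop("bounds must be finite with lower <= upper", call. = FALSE)
  if (budget < 1) stop("budget must be >= 1", call. = FALSE)
  bad <- setdiff(freeParams, names(spec$params))
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  evalSpec <- spec
  evalSpec$nReplicates <- as.integer(nReplicatesSearch)
  objective <- function(x) {
    p <- evalSpec$params
    p[freeParams] <- as.list(x)
    s <- evalSpec
    s$params <- p
    calibration_loss(run_scenario(s), targets)
  }

  set.seed(as.integer(seed))
  nSeeding <- max(1L, min(budget, ceiling(0.6 * budget)))
  pts <- lhs::randomLHS(nSeeding, k)
  cand <- sweep(sweep(pts, 2L, upper - lower, "*"), 2L, lower, "+")
  if (budget == 1L) cand <- cand[1L, , drop = FALSE]

  trace <- matrix(NA_real_, budget, k + 1L,
                  dimnames = list(NULL, c(freeParams, "loss")))
  bestX <- NULL
  bestLoss <- Inf
  nEval <- 0L
  for (i in seq_len(nrow(cand))) {
    x <- cand[i, ]
    loss <- objective(x)
    nEval <- nEval + 1L
    trace[nEval, ] <- c(x, loss)
    if (loss < bestLoss) { bestLoss <- loss; bestX <- x }
  }
  radius <- 0.25
  while (nEval < budget) {
    x <- bestX + radius * (upper - lower) * stats::rnorm(k)
    x <- pmin(upper, pmax(lower, x))
    loss <- objective(x)
    nEval <- nEval + 1L
    trace[nEval, ] <- c(x, loss)
    if (loss < bestLoss) { bestLoss <- loss; bestX <- x }
    radius <- max(0.02, radius * 0.97)
  }

  bestParams <- spec$params
  bestParams[freeParams] <- as.list(bestX)
  structure(list(params = bestParams,
                 best = stats::setNames(as.numeric(bestX), freeParams),
                 loss = bestLoss,
                 trace = as.data.frame(trace),
                 evaluations = nEval),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> %d evaluations, best loss %.4g\n",
              x$evaluations, x$loss))
  print(round(x$best, 4))
  invisible(x)
}

#' Backward validation against observed confidence intervals
#'
#' For every target (year, product), checks whether the replicate-mean
#' simulated prevalence lies inside the observed 95% confidence interval.
#' This mirrors the study design: initialise in the first survey year,
#' simulate forward, and ask how many subsequent survey points the model
#' reproduces within sampling uncertainty.
#'
#' @param result a `scenario_result` whose years cover the targets.
#' @param targets targets data frame ([load_targets()]).
#' @return List of class `validation_report`: `table` (year, product, sim,
#'   obs, ciLow, ciHigh, hit), `hits`, `misses`.
#' @export
validate_backward <- function(result, targets) {
  sim <- simulated_at_targets(result, targets)
  hit <- sim >= targets$ciLow & sim <= targets$ciHigh
  tab <- data.frame(year = targets$year, product = targets$product,
                    sim = sim, obs = targets$prev,
                    ciLow = targets$ciLow, ciHigh = targets$ciHigh,
                    hit = hit)
  structure(list(table = tab, hits = sum(hit), misses = sum(!hit)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d hits / %d targets inside the 95%% CI\n",
              x$hits, x$hits + x$misses))
  tab <- x$table
  tab[c("sim", "obs", "ciLow", "ciHigh")] <-
    round(100 * tab[c("sim", "obs", "ciLow", "ciHigh")], 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Counterfactual openness x crossover scenario grid
#'
#' Runs [run_scenario()] for every combination of openness offset (applied
#' jointly to both products, `thetaCC = thetaEC = theta`) and crossover
#' value, and tabulates the horizon-year mean and SD of each state fraction.
#' The default grid is the 4 x 4 lattice 0, 0.1, 0.2, 0.3 on each axis.
#'
#' @param baseSpec a `scenario_spec`; its `thetaCC/thetaEC/crossover` are
#'   overridden cell by cell.
#' @param thetaValues,crossoverValues numeric vectors of scenario values
#'   (warning outside \[0, 0.3\]).
#' @return A `data.frame` with columns `theta, crossover,
#'   fracCCOnly_mean, fracECOnly_mean, fracDual_mean, fracNone_mean` and the
#'   matching `_sd` columns, one row per cell in fixed (theta-major) order.
#' @export
run_grid <- function(baseSpec, thetaValues = seq(0, 0.3, by = 0.1),
                     crossoverValues = seq(0, 0.3, by = 0.1)) {
  if (!length(thetaValues) || !length(crossoverValues))
    stop("value lists must be non-empty", call. = FALSE)
  cells <- expand.grid(crossover = crossoverValues, theta = thetaValues)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    th <- cells$theta[i]; ch <- cells$crossover[i]
    spec <- baseSpec
    spec$params$thetaCC <- th
    spec$params$thetaEC <- th
    spec$params$crossover <- ch
    validate_parameters(spec$params)
    res <- run_scenario(spec)
    horizon <- nrow(res$perYearMean)
    mu <- res$perYearMean[horizon, ]
    sd <- res$perYearSD[horizon, ]
    data.frame(theta = th, crossover = ch,
               fracCCOnly_mean = mu[["CC_ONLY"]],
               fracECOnly_mean = mu[["EC_ONLY"]],
               fracDual_mean = mu[["DUAL"]],
               fracNone_mean = mu[["NONE"]],
               fracCCOnly_sd = sd[["CC_ONLY"]],
               fracECOnly_sd = sd[["EC_ONLY"]],
               fracDual_sd = sd[["DUAL"]],
               fracNone_sd = sd[["NONE"]])
  })
  out <- do.call(rbind, rows)
  out[order(out$theta, out$crossover), , drop = FALSE]
}
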