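#' Recipe for a synthetic breath-test cohort
#'
#' Describes a cohort of simulated 13C-octanoic-acid breath-test subjects
#' whose underlying excretion curve is `y = a * t^b * exp(-c*t)`. Each
#' subject carries a lognormal multiplicative effect on the scale `a`
#' (sdlog `subjectSd`), mimicking inter-individual variation without
#' modelling it mechanistically, plus gaussian measurement noise with
#' standard deviation `noiseSd` times the curve peak. Designated subjects
#' receive artifacts so that every selection policy has something to act
#' on: "negative" subjects get one sample forced below zero, "outlier"
#' subjects have all values multiplied by `outlierScale`. The pre-dose
#' baseline sample (time `<= 0`) is generated as noise around zero.
#'
#' @param nSubjects number of subjects.
#' @param arm treatment arm label (`"PB"` or `"SO"`).
#' @param a,b,c generating curve constants.
#' @param noiseSd measurement noise, as a fraction of the curve peak.
#' @param subjectSd sdlog of the per-subject lognormal scale effect.
#' @param sampleTimes sampling protocol (min); the default is the
#'   breath-test protocol: one pre-meal sample and samples to 240 min.
#' @param nNegative,nOutlier number of artifact subjects (the last ids).
#' @param outlierScale multiplier applied to outlier subjects.
#' @param seed RNG seed; every generated cohort is a pure function of the
#'   recipe.
#' @return a recipe list for [makeCohort()].
#' @export
cohortRecipe <- function(nSubjects = 8, arm = "PB",
                         a = 0.289, b = 1.05, c = 0.011,
                         noiseSd = 0.1, subjectSd = 0.1,
                         sampleTimes = c(-15, 15, 30, 45, 60, 75, 90, 105,
                                         120, 180, 210, 240),
                         nNegative = 0, nOutlier = 0, outlierScale = 3,
                         seed = 1) {
  stopifnot(nSubjects >= 1, nNegative + nOutlier <= nSubjects,
            noiseSd >= 0, subjectSd >= 0, a > 0, b > 0, c > 0)
  list(nSubjects = nSubjects, arm = arm, a = a, b = b, c = c,
       noiseSd = noiseSd, subjectSd = subjectSd, sampleTimes = sampleTimes,
       nNegative = nNegative, nOutlier = nOutlier,
       outlierScale = outlierScale, seed = seed)
}

# run code under a local RNG seed without disturbing the caller's stream
withLocalSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic breath-test cohort
#'
#' @param recipe a [cohortRecipe()].
#' @return a cohort data.frame (`subject_id`, `arm`, `time_min`,
#'   `dose_per_h`), deterministic given the recipe's seed.
#' @examples
#' cohort <- makeCohort(cohortRecipe(nSubjects = 3, noiseSd = 0))
#' head(cohort)
#' @export
makeCohort <- function(recipe) {
  withLocalSeed(recipe$seed, {
    peak <- recipe$a * (recipe$b / recipe$c)^recipe$b * exp(-recipe$b)
    rows <- vector("list", recipe$nSubjects)
    # artifact subjects occupy the last ids, outliers after negatives
    negIds <- if (recipe$nNegative)
      seq(recipe$nSubjects - recipe$nNegative - recipe$nOutlier + 1,
          length.out = recipe$nNegative) else integer(0)
    outIds <- if (recipe$nOutlier)
      seq(recipe$nSubjects - recipe$nOutlier + 1,
          length.out = recipe$nOutlier) else integer(0)
    for (i in seq_len(recipe$nSubjects)) {
      eff <- exp(stats::rnorm(1, 0, recipe$subjectSd))
      tt <- recipe$sampleTimes
      y <- ifelse(tt > 0,
                  recipe$a * eff * tt^recipe$b * exp(-recipe$c * tt), 0)
      y <- y + stats::rnorm(length(tt), 0, recipe$noiseSd * peak)
      # pre-dose baselines are noise around zero, floored so that negative
      # enrichment stays an injected artifact, not a coin flip
      y[tt <= 0] <- pmax(0, y[tt <= 0])
      if (i %in% outIds) y <- y * recipe$outlierScale
      if (i %in% negIds && !any(y < 0))
        y[which.min(y)] <- -0.02 * peak
      rows[[i]] <- data.frame(subject_id = i, arm = recipe$arm,
                              time_min = tt, dose_per_h = y,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Toy three-component network
#'
#' A minimal example network for exercising the builder and simulator:
#' components `C1` (inputs `A`, `D`; output `B`), `C2` (input `B`; output
#' `C`) and `C3` (inputs `B` and `C`, the latter disconnected via
#' `Connect = No`; output `D`), with an external pulse of 20 units on `A`
#' at `t = 0` and zeros thereafter. The registered functions are sums of
#' the connected inputs, so a pulse propagates one channel per cycle:
#' `A -> B -> {C, D}`, and `D` feeds back into `C1`.
#'
#' @param timeGrid header time grid (min); the default matches a 5-min
#'   cycle over 8 cycles.
#' @return `list(spec = <ModelSpecTable>, registry = <registry>)`.
#' @examples
#' toy <- makeToyNetwork()
#' res <- simulateNetwork(buildModel(toy$spec, toy$registry),
#'                        tEnd = 35, dt = 5)
#' trajectories(res)
#' @export
makeToyNetwork <- function(timeGrid = seq(0, 35, by = 5)) {
  rows <- data.frame(
    component = c("C1", "C1", "C1", "C2", "C2", "C3", "C3", "C3"),
    connect = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    port = c("A", "D", "B", "B", "C", "B", "C", "D"),
    direction = c("input", "input", "output", "input", "output",
                  "input", "input", "output"),
    stringsAsFactors = FALSE)
  data <- matrix(NA_real_, nrow(rows), length(timeGrid))
  data[1, ] <- c(20, rep(0, length(timeGrid) - 1))
  spec <- modelSpecTable(rows, data, timeGrid)
  sumFun <- function(out) {
    force(out)
    function(inputs, state, time, dt)
      list(outputs = stats::setNames(sum(inputs), out), state = state)
  }
  reg <- functionRegistry()
  registerFunction(reg, "C1", sumFun("B"))
  registerFunction(reg, "C2", sumFun("C"))
  registerFunction(reg, "C3", sumFun("D"))
  list(spec = spec, registry = reg)
}

#' Simulate-then-observe gastric dataset
#'
#' Closes the loop for recovery tests: simulates the gastric feedback model
#' under placebo conditions, converts the per-minute emptying rate into a
#' percent-dose/h curve (the emptied fraction per minute, expressed per
#' hour as percent of the meal), fits the excretion-curve family
#' `a * t^b * exp(-c*t)` to it, and samples a synthetic cohort from the
#' fitted curve -- so the cohort's true underlying half-emptying time is
#' known from the simulation itself.
#'
#' @param params parameter lists as for [runScenario()].
#' @param recipe a [cohortRecipe()]; its `a`, `b`, `c` are replaced by the
#'   fitted values.
#' @param horizon simulation length (min).
#' @return list with `cohort`, `trueThalf` (the simulation's interpolated
#'   half-emptying time), `curve` (the fitted generating constants) and
#'   `scenario`.
#' @export
makeObservedGastricDataset <- function(params = list(),
                                       recipe = cohortRecipe(),
                                       horizon = 480) {
  sc <- runScenario(params, horizon = horizon)
  ret <- retentionCurve(sc)
  meal <- ret$retained[1]
  rate <- -diff(ret$retained) / diff(ret$time)        # caloric units / min
  tt <- utils::tail(ret$time, -1)
  y <- 100 * 60 * rate / meal                          # % dose / h
  fit0 <- minpack.lm::nlsLM(
    y ~ exp(la) * tt^exp(lb) * exp(-exp(lc) * tt),
    data = data.frame(tt = tt, y = y),
    start = list(la = log(0.3), lb = log(1), lc = log(0.01)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- exp(stats::coef(fit0))
  recipe$a <- unname(cf["la"]); recipe$b <- unname(cf["lb"])
  recipe$c <- unname(cf["lc"])
  list(cohort = makeCohort(recipe), trueThalf = scenarioThalf(sc),
       curve = c(a = recipe$a, b = recipe$b, c = recipe$c), scenario = sc)
}
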