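#' Read or write a breath-test cohort
#'
#' Cohorts are delimited text with columns `subject_id`, `arm` (`PB` or
#' `SO`), `time_min` and `dose_per_h` (percent 13C dose per hour). Series
#' may contain negative values: these are measurement artifacts, kept on
#' read because the `S2` selection policy is defined by their presence.
#'
#' @param path file path.
#' @param cohort a cohort data.frame.
#' @return `readCohort()`: a data.frame with the four columns above,
#'   ordered by subject and time.
#' @export
readCohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "arm", "time_min", "dose_per_h")
  if (!all(need %in% names(x)))
    stop("cohort file must have columns ", paste(need, collapse = ", "))
  x <- x[order(x$subject_id, x$time_min), need]
  rownames(x) <- NULL
  x
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

# pooled positive-time points of a cohort
pooledPoints <- function(cohort) {
  keep <- cohort$time_min > 0
  data.frame(t = cohort$time_min[keep], y = cohort$dose_per_h[keep])
}

#' Fit the population excretion curve
#'
#' Nonlinear least squares of `y = a * t^b * exp(-c*t)` on the points of
#' all subjects pooled together (a population model: one curve for all
#' data). Only strictly positive sample times enter the fit (the pre-dose
#' baseline carries no excretion signal). Positivity of `(a, b, c)` is
#' enforced by optimising on the log scale, and the optimiser is restarted
#' from a coarse grid of initial values, keeping the fit with the smallest
#' residual sum of squares.
#'
#' @param cohort a cohort data.frame (see [readCohort()]).
#' @param startGrid named list of starting values tried in full factorial
#'   combination.
#' @return a [BreathCurveFit-class].
#' @examples
#' cohort <- makeCohort(cohortRecipe(nSubjects = 4, noiseSd = 0, seed = 1))
#' fit <- fitPopulationCurve(cohort)
#' curveCoef(fit)
#' @export
fitPopulationCurve <- function(cohort,
                               startGrid = list(a = c(0.1, 0.3, 1),
                                                b = c(0.5, 1, 2),
                                                c = c(0.005, 0.01, 0.02))) {
  pts <- pooledPoints(cohort)
  if (length(unique(pts$t)) < 3)
    stop("need at least 3 distinct positive time points")
  starts <- expand.grid(startGrid)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ exp(la) * t^exp(lb) * exp(-exp(lc) * t),
        data = pts,
        start = list(la = log(starts$a[i]), lb = log(starts$b[i]),
                     lc = log(starts$c[i])),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(coef = exp(stats::coef(fit)), rss = rss)
  }
  if (is.null(best))
    stop("curve fit did not converge from any start of the grid (",
         nrow(starts), " starts)")
  new("BreathCurveFit", a = unname(best$coef["la"]),
      b = unname(best$coef["lb"]), c = unname(best$coef["lc"]),
      rss = best$rss, nPoints = nrow(pts))
}

#' Lag time of the excretion curve
#'
#' The time at which `a * t^b * exp(-c*t)` attains its maximum: `b / c`.
#'
#' @param fit a [BreathCurveFit-class], or a named vector/list with `b`, `c`.
#' @return lag time (min).
#' @examples
#' tlagFromFit(c(a = 1, b = 1, c = 0.01))   # 100
#' @export
tlagFromFit <- function(fit) {
  p <- asCurveParams(fit)
  if (p[["c"]] <= 0) stop("c must be > 0")
  p[["b"]] / p[["c"]]
}

#' Half-excretion time of the excretion curve
#'
#' The time by which half of the total (asymptotic) cumulative 13C
#' excretion has occurred: the `t*` solving
#' `integral(0, t*) t^b exp(-c t) dt = 1/2 integral(0, Inf)`. Since the
#' integrand is an unnormalised gamma density with shape `b + 1` and rate
#' `c`, `t*` is its median, computed through the inverse regularized lower
#' incomplete gamma function.
#'
#' @param fit a [BreathCurveFit-class], or a named vector/list with `b`, `c`.
#' @return half-excretion time (min).
#' @examples
#' thalfFromFit(c(a = 1, b = 0, c = 0.01))  # pure exponential: log(2)/c
#' @export
thalfFromFit <- function(fit) {
  p <- asCurveParams(fit)
  if (p[["b"]] < 0 || p[["c"]] <= 0) stop("need b >= 0 and c > 0")
  stats::qgamma(0.5, shape = p[["b"]] + 1, rate = p[["c"]])
}

asCurveParams <- function(fit) {
  if (is(fit, "BreathCurveFit")) curveCoef(fit)
  else unlist(fit)[c("a", "b", "c")]
}

#' Cumulative 13C dose of one subject's series
#'
#' Trapezoidal integration of percent dose/h over time in hours, reported
#' at each sample time (zero at the first).
#'
#' @param series data.frame with columns `time_min` and `dose_per_h`,
#'   strictly increasing times, at least 2 points.
#' @return data.frame with columns `time_min` and `cum_dose` (percent).
#' @examples
#' cumulativeDose(data.frame(time_min = c(0, 60), dose_per_h = c(1, 1)))
#' @export
cumulativeDose <- function(series) {
  if (nrow(series) < 2) stop("need at least 2 points")
  if (any(diff(series$time_min) <= 0)) stop("times must be increasing")
  th <- series$time_min / 60
  y <- series$dose_per_h
  inc <- diff(th) * (utils::head(y, -1) + utils::tail(y, -1)) / 2
  data.frame(time_min = series$time_min, cum_dose = c(0, cumsum(inc)))
}

#' Chi-squared outlier scores per subject
#'
#' Scores each subject by the squared standardised deviation of its mean
#' measurement from the cohort: `score_i = (x_i - xbar)^2 / s^2` with `x_i`
#' the mean of subject `i`'s measurements, `xbar` the mean of the `x_i`,
#' and `s` their sample (n-1) standard deviation. A subject scoring above 1
#' is classified an outlier by the `S3` selection policy.
#'
#' @param cohort a cohort data.frame with at least 2 subjects.
#' @return named numeric vector of scores, one per subject.
#' @examples
#' # subject means 10, 12, 20 give scores 16/28, 4/28, 36/28
#' @export
chiSquaredScores <- function(cohort) {
  means <- tapply(cohort$dose_per_h, cohort$subject_id, mean)
  if (length(means) < 2) stop("need at least 2 subjects")
  s2 <- stats::var(as.vector(means))
  if (s2 == 0) stop("all subject means identical: score undefined (s = 0)")
  scores <- (as.vector(means) - mean(means))^2 / s2
  stats::setNames(scores, names(means))
}

#' Apply a data-selection policy to a cohort
#'
#' \describe{
#'   \item{S1}{the complete data set.}
#'   \item{S2}{drop every subject whose series contains one or more
#'     negative enrichment values.}
#'   \item{S3}{drop every subject whose [chiSquaredScores()] exceeds 1,
#'     then drop any `manualExclusions` (an explicit user override for
#'     subjects judged implausible on other grounds; never automatic).}
#' }
#' The applied selection is attached as the `"selectionLog"` attribute
#' (subject, kept, reason).
#'
#' @param cohort a cohort data.frame.
#' @param policy `"S1"`, `"S2"` or `"S3"`.
#' @param manualExclusions subject ids to drop in addition (S3 only).
#' @return the selected cohort subset (error if empty).
#' @examples
#' cohort <- makeCohort(cohortRecipe(nSubjects = 5, nNegative = 1, seed = 7))
#' nrow(selectSubjects(cohort, "S2")) < nrow(cohort)
#' @export
selectSubjects <- function(cohort, policy = c("S1", "S2", "S3"),
                           manualExclusions = integer(0)) {
  policy <- match.arg(policy)
  if (!nrow(cohort)) stop("empty cohort")
  ids <- unique(cohort$subject_id)
  reason <- stats::setNames(rep("", length(ids)), ids)
  keep <- stats::setNames(rep(TRUE, length(ids)), ids)
  if (policy == "S2") {
    for (id in ids)
      if (any(cohort$dose_per_h[cohort$subject_id == id] < 0)) {
        keep[as.character(id)] <- FALSE
        reason[as.character(id)] <- "negative enrichment value"
      }
  } else if (policy == "S3") {
    sc <- chiSquaredScores(cohort)
    for (id in names(sc))
      if (sc[[id]] > 1) {
        keep[id] <- FALSE
        reason[id] <- sprintf("chi-squared score %.3g > 1", sc[[id]])
      }
    for (id in manualExclusions)
      if (as.character(id) %in% names(keep)) {
        keep[as.character(id)] <- FALSE
        reason[as.character(id)] <-
          paste(reason[as.character(id)], "manual exclusion")
      }
  }
  kept <- ids[keep[as.character(ids)]]
  if (!length(kept)) stop("selection ", policy, " removed every subject")
  out <- cohort[cohort$subject_id %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "selectionLog") <- data.frame(
    subject = ids, kept = as.vector(keep),
    reason = trimws(as.vector(reason)), stringsAsFactors = FALSE)
  out
}
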