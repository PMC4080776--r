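#' Parameters of the gastric-emptying feedback model
#'
#' Parameter sets for the three components of the stomach-intestine-CNS
#' feedback network. Defaults are the model's reference configuration: the
#' four free parameters (`k`, `THD`, `IR_TR`, `INV_DR`) at their calibrated
#' placebo values and the fixed constants at their anatomically or
#' kinetically derived values.
#'
#' \describe{
#'   \item{`k`}{gastric emptying rate constant (1/min). The retention curve
#'     is `NUT_INP(t) = NUT_INP(0) * (1 - (1 - exp(-k t))^b)` with
#'     `b = exp(k * T_LAG)`.}
#'   \item{`T_LAG`}{initial delay of gastric emptying (min), pinned to the
#'     lag time estimated from breath-test data.}
#'   \item{`THD`}{efferent signal threshold (dimensionless, in `[0, 1)`): a
#'     brake event fires when the sigmoid-transformed efferent signal
#'     strictly exceeds it.}
#'   \item{`IR_TR`}{intestinal-response transfer rate constant (1/E) inside
#'     the sigmoid [sgmd()].}
#'   \item{`BRK`}{brake constant: each brake event multiplies `k` by
#'     `1 - BRK`. The default 0.03 derives from requiring 15 consecutive
#'     events to stretch a 155-min half-emptying time to 237 min
#'     ([brkFromThalfShift()]).}
#'   \item{`CAL_GRD`}{caloric grade: fraction of emptied calories assumed
#'     absorbed by the ileum and driving the afferent signal; 0.6 from the
#'     ileal share of small-intestinal length ([calGrdFromLengths()]).}
#'   \item{`INV_DR`}{in-vivo decay rate constant `c` (1/min) of the vagal
#'     afferent impulse response.}
#'   \item{`T_MAX`}{time at maximum afferent amplitude (min); the impulse
#'     response peaks exactly `T_MAX` minutes after a nutrient bolus.}
#'   \item{`TRF_K`}{CNS afferent-to-efferent transfer constant
#'     (dimensionless); 1 means direct proportional unit transfer, 0 opens
#'     the feedback loop.}
#' }
#'
#' @param k,T_LAG,THD,IR_TR,BRK,CAL_GRD numeric, see above.
#' @return a validated named list.
#' @examples
#' stomachParams(k = 0.009, T_LAG = 91.72)
#' @export
stomachParams <- function(k = 0.009, T_LAG = 91.72, THD = 0.45,
                          IR_TR = 0.3, BRK = 0.03, CAL_GRD = 0.6) {
  stopifnot(k > 0, T_LAG >= 0, THD >= 0, THD < 1, IR_TR >= 0,
            BRK >= 0, BRK < 1, CAL_GRD > 0, CAL_GRD <= 1)
  list(k = k, T_LAG = T_LAG, THD = THD, IR_TR = IR_TR, BRK = BRK,
       CAL_GRD = CAL_GRD)
}

#' @rdname stomachParams
#' @param INV_DR,T_MAX numeric, see above.
#' @export
intestineParams <- function(INV_DR = 0.1, T_MAX = 10) {
  stopifnot(INV_DR > 0, T_MAX > 0)
  list(INV_DR = INV_DR, T_MAX = T_MAX, bResp = T_MAX * INV_DR)
}

#' @rdname stomachParams
#' @param TRF_K numeric, see above.
#' @export
cnsParams <- function(TRF_K = 1) {
  stopifnot(TRF_K >= 0)
  list(TRF_K = TRF_K)
}

#' Fraction of a meal retained by the stomach
#'
#' The power-exponential retention curve
#' `1 - (1 - exp(-k t))^b`: 1 at `t = 0`, tending to 0, with the shape
#' parameter `b >= 1` carrying the initial lag phase.
#'
#' @param t time since meal intake (min), `>= 0`.
#' @param k gastric emptying rate constant (1/min), `> 0`.
#' @param b shape parameter, `>= 1`; for lag `T_LAG`, `b = exp(k * T_LAG)`.
#' @return fraction in `[0, 1]`.
#' @examples
#' retainedFraction(0, 0.009, 2.283)    # full stomach
#' retainedFraction(1e5, 0.009, 2.283)  # empty in the limit
#' @export
retainedFraction <- function(t, k, b) {
  if (any(t < 0)) stop("t must be >= 0")
  if (k <= 0) stop("k must be > 0")
  if (any(b < 1)) stop("b must be >= 1")
  # 1 - (1 - e^(-kt))^b, computed in logs for accuracy near t = 0 and t -> Inf
  lg <- log(-expm1(-k * t))          # log(1 - e^(-kt)); -Inf at t = 0
  ifelse(t == 0, 1, -expm1(b * lg))
}

# inverse of retainedFraction in t at fixed (k, b): the virtual time at
# which the curve passes through the given fraction
solveVirtualTime <- function(fraction, k, b) {
  if (fraction >= 1) return(0)
  if (fraction <= 0) return(Inf)
  # (1 - e^(-kt))^b = 1 - fraction  =>  t = -log(1 - (1-fraction)^(1/b))/k
  -log(-expm1(log1p(-fraction) / b)) / k
}

#' Sigmoid efferent transfer function
#'
#' Maps the vagal efferent signal to a brake drive in `[0, 1)`:
#' `sgmd(x) = 2 / (1 + exp(-IR_TR * x)) - 1`, zero at `x = 0`, monotone
#' increasing and saturating at 1.
#'
#' @param irVe vagal efferent signal (E units), `>= 0`.
#' @param irTr transfer rate constant (1/E).
#' @return dimensionless value in `[0, 1)`.
#' @examples
#' sgmd(0, 0.3)   # 0
#' sgmd(1, 0.3)   # ~0.149
#' @export
sgmd <- function(irVe, irTr) {
  if (any(irVe < 0)) stop("irVe must be >= 0")
  2 / (1 + exp(-irTr * irVe)) - 1
}

#' Create a stomach state
#'
#' @param params a [stomachParams()] list.
#' @return opaque state list used by [emptiedIncrement()] and
#'   [applyBrake()]: zero load, `k` and `b` at their initial values.
#' @export
newStomachState <- function(params) {
  list(load = 0, retained = 0,
       k = params$k, b = exp(params$k * params$T_LAG),
       tau = 0, brakeCount = 0L, lastWrite = 0, prevAbove = FALSE)
}

# fold newly arrived calories into the stomach, preserving the absolute
# retained amount (virtual time re-solved for the new fraction)
stomachIntake <- function(state, amount) {
  if (amount <= 0) return(state)
  state$load <- state$load + amount
  state$retained <- state$retained + amount
  state$tau <- solveVirtualTime(state$retained / state$load, state$k, state$b)
  state
}

#' Advance the stomach by one cycle and return the emptied calories
#'
#' Computes the calories expelled over a step `dt` as the exact difference
#' of the retention curve along the stomach's virtual time, then scales by
#' the caloric grade: `NUT = (retained(tau) - retained(tau + dt)) * CAL_GRD`.
#' Using the exact difference (rather than a derivative approximation) makes
#' the emptied amounts telescope: with `CAL_GRD = 1` they sum exactly to the
#' initial load.
#'
#' @param state a stomach state (see [newStomachState()]).
#' @param params a [stomachParams()] list.
#' @param dt step (min), `> 0`.
#' @return `list(state = <advanced state>, nut = <calories delivered to the
#'   intestine>)`; `nut` is never negative.
#' @export
emptiedIncrement <- function(state, params, dt = 1) {
  stopifnot(dt > 0)
  if (state$load <= 0 || state$retained <= 0)
    return(list(state = state, nut = 0))
  state$tau <- state$tau + dt
  newRetained <- state$load * retainedFraction(state$tau, state$k, state$b)
  raw <- max(0, state$retained - newRetained)
  state$retained <- state$retained - raw
  list(state = state, nut = raw * params$CAL_GRD)
}

#' Apply one ileal-brake event to the stomach
#'
#' If the sigmoid-transformed efferent signal strictly exceeds the threshold
#' `THD`, the emptying rate constant is reduced multiplicatively,
#' `k <- k * (1 - BRK)`, the shape parameter is recomputed as
#' `b = exp(k * T_LAG)`, and the stomach's virtual time is re-solved so that
#' the retained fraction is continuous across the event (the retention
#' trajectory has no jump). Intended to be called at most once per
#' simulation cycle, capping the brake rate at one event per cycle.
#'
#' @param state a stomach state.
#' @param params a [stomachParams()] list.
#' @param irVe the efferent signal presented at the current cycle.
#' @return `list(state = <state>, fired = <logical>)`.
#' @examples
#' st <- newStomachState(stomachParams())
#' applyBrake(st, stomachParams(), irVe = 0)$fired   # below threshold
#' @export
applyBrake <- function(state, params, irVe) {
  s <- sgmd(irVe, params$IR_TR)
  if (!(s > params$THD))
    return(list(state = state, fired = FALSE))
  state$k <- state$k * (1 - params$BRK)
  state$b <- exp(state$k * params$T_LAG)
  if (state$load > 0) {
    frac <- state$retained / state$load
    if (frac > 0 && frac <= 1) {
      state$tau <- solveVirtualTime(frac, state$k, state$b)
    } else {
      state$tau <- if (frac > 1) 0 else state$tau
      warning("brake re-solve: retained fraction ", signif(frac, 4),
              " outside (0,1]; virtual time clamped")
    }
  }
  state$brakeCount <- state$brakeCount + 1L
  list(state = state, fired = TRUE)
}

#' Vagal afferent response to past intestinal nutrient arrivals
#'
#' Superposition of impulse responses: a nutrient amount `A` arriving at
#' time `t0` contributes `A * (c*e/b)^b * s^b * exp(-c*s)` at lag
#' `s = t - t0`, where `c = INV_DR` and `b = T_MAX * c`. The normalisation
#' `(c*e/b)^b` makes each bolus's response peak exactly at lag `T_MAX` with
#' peak value equal to the bolus amount, for any `INV_DR > 0`. Lags `<= 0`
#' contribute nothing; the response is linear in the amounts.
#'
#' @param arrivalTimes,amounts numeric vectors: past nutrient arrivals
#'   (min, caloric units).
#' @param t evaluation time (min), `>=` all arrival times.
#' @param params an [intestineParams()] list.
#' @return afferent signal in E units.
#' @examples
#' p <- intestineParams(INV_DR = 0.1, T_MAX = 10)
#' afferentResponse(0, 1, t = 10, p)   # unit bolus peaks at T_MAX: exactly 1
#' @export
afferentResponse <- function(arrivalTimes, amounts, t, params) {
  stopifnot(length(arrivalTimes) == length(amounts))
  if (!length(amounts)) return(0)
  if (any(amounts < 0)) stop("amounts must be >= 0")
  s <- t - arrivalTimes
  keep <- s > 0
  if (!any(keep)) return(0)
  s <- s[keep]
  b <- params$bResp; cc <- params$INV_DR
  sum(amounts[keep] * (cc * exp(1) / b)^b * s^b * exp(-cc * s))
}

#' CNS efferent response
#'
#' Direct proportional transfer of the afferent signal:
#' `IR_VE = TRF_K * IR_VA`. The engine's one-cycle channel delay delivers it
#' to the stomach in the following cycle. `TRF_K = 0` opens the feedback
#' loop.
#'
#' @param irVa afferent signal (E units), `>= 0`.
#' @param params a [cnsParams()] list.
#' @return efferent signal (E units).
#' @export
efferentResponse <- function(irVa, params) {
  if (any(irVa < 0)) stop("irVa must be >= 0")
  params$TRF_K * irVa
}

#' Brake constant from a half-emptying-time shift
#'
#' The per-event brake fraction that stretches a half-emptying time from
#' `thalfLo` to `thalfHi` in `nEvents` multiplicative steps:
#' `(thalfHi/thalfLo)^(1/nEvents) - 1`.
#'
#' @param thalfLo,thalfHi half-emptying times (min), `thalfHi >= thalfLo > 0`.
#' @param nEvents number of brake events, `>= 1`.
#' @param round round to the nearest whole percent (the convention used for
#'   the shipped default `BRK = 0.03`).
#' @return brake fraction.
#' @examples
#' brkFromThalfShift(155, 237, 15)                 # 0.03
#' brkFromThalfShift(155, 237, 15, round = FALSE)  # ~0.0287
#' @export
brkFromThalfShift <- function(thalfLo, thalfHi, nEvents, round = TRUE) {
  stopifnot(thalfLo > 0, thalfHi >= thalfLo, nEvents >= 1)
  brk <- (thalfHi / thalfLo)^(1 / nEvents) - 1
  if (round) round(brk, 2) else brk
}

#' Caloric grade from small-intestinal segment lengths
#'
#' Assuming uniform distribution and absorption of calories along the small
#' intestine and a constant radius, the fraction absorbed by the ileum is
#' its share of the total length.
#'
#' @param duodenum,jejunum,ileum segment lengths (cm), `> 0`.
#' @param round round to the nearest 10\% (the convention used for the
#'   shipped default `CAL_GRD = 0.6`).
#' @return ileal fraction.
#' @examples
#' calGrdFromLengths(25, 260, 395)                 # 0.6
#' calGrdFromLengths(25, 260, 395, round = FALSE)  # ~0.581
#' @export
calGrdFromLengths <- function(duodenum, jejunum, ileum, round = TRUE) {
  stopifnot(duodenum > 0, jejunum > 0, ileum > 0)
  total <- duodenum + jejunum + ileum
  frac <- ileum / total
  if (round) round(frac, 1) else frac
}

#' Transfer functions of the gastric feedback network
#'
#' Builds a function registry with the three components of the gastric
#' model, closed over their parameter lists:
#' \describe{
#'   \item{Stomach}{reads `NUT_INP` (new calories are recognised as the
#'     presented value in excess of its own previous retention write) and
#'     `IR_VE`; applies at most one brake event per cycle, then empties by
#'     the exact retention-curve difference; writes `NUT` (emptied calories
#'     times `CAL_GRD`) and `NUT_INP` (current retention).}
#'   \item{Intestine}{reads `NUT` (meal-derived chyme superimposed with any
#'     infusion attached to the channel), accumulates the arrival history
#'     and writes the convolved afferent signal `IR_VA`.}
#'   \item{CNS}{reads `IR_VA`, writes `IR_VE = TRF_K * IR_VA` and the
#'     declared-but-undefined `VAS` output as constant 0.}
#' }
#'
#' @param stomach,intestine,cns parameter lists (see [stomachParams()]).
#' @param brakeTrigger `"level"` (default): a brake fires in every cycle in
#'   which the sigmoid signal exceeds `THD`, i.e. at the maximum rate of one
#'   event per cycle. `"edge"`: a brake fires only in cycles where the
#'   signal exceeds `THD` after not exceeding it in the previous cycle (each
#'   onset of exceedance). See the package vignette for why both readings
#'   are provided.
#' @return a function registry (see [registerFunction()]) with keys
#'   `Stomach`, `Intestine`, `CNS`.
#' @examples
#' reg <- gastricRegistry(stomachParams(), intestineParams(), cnsParams())
#' registryKeys(reg)
#' @export
gastricRegistry <- function(stomach = stomachParams(),
                            intestine = intestineParams(),
                            cns = cnsParams(),
                            brakeTrigger = c("level", "edge")) {
  brakeTrigger <- match.arg(brakeTrigger)
  reg <- functionRegistry()
  registerFunction(reg, "Stomach", function(inputs, state, time, dt) {
    if (is.null(state)) state <- newStomachState(stomach)
    nutInp <- if ("NUT_INP" %in% names(inputs)) inputs[["NUT_INP"]] else 0
    irVe <- if ("IR_VE" %in% names(inputs)) inputs[["IR_VE"]] else 0
    state <- stomachIntake(state, nutInp - state$lastWrite)
    events <- character(0)
    above <- sgmd(irVe, stomach$IR_TR) > stomach$THD
    eligible <- if (brakeTrigger == "level") above else above && !state$prevAbove
    state$prevAbove <- above
    if (eligible && state$load > 0) {
      br <- applyBrake(state, stomach, irVe)
      state <- br$state
      if (br$fired)
        events <- sprintf("brake %d: k = %.6g", state$brakeCount, state$k)
    }
    adv <- emptiedIncrement(state, stomach, dt)
    state <- adv$state
    state$lastWrite <- state$retained
    list(outputs = c(NUT = adv$nut, NUT_INP = state$retained),
         state = state, events = events)
  })
  registerFunction(reg, "Intestine", function(inputs, state, time, dt) {
    if (is.null(state))
      state <- list(times = numeric(0), amounts = numeric(0))
    nut <- if ("NUT" %in% names(inputs)) inputs[["NUT"]] else 0
    if (nut > 0) {
      state$times <- c(state$times, time - dt)
      state$amounts <- c(state$amounts, nut)
    }
    irVa <- afferentResponse(state$times, state$amounts, time, intestine)
    list(outputs = c(IR_VA = irVa), state = state)
  })
  registerFunction(reg, "CNS", function(inputs, state, time, dt) {
    irVa <- if ("IR_VA" %in% names(inputs)) inputs[["IR_VA"]] else 0
    list(outputs = c(IR_VE = efferentResponse(irVa, cns), VAS = 0),
         state = state)
  })
  reg
}

#' Structural specification of the gastric feedback network
#'
#' Builds the three-component stomach-intestine-CNS specification table
#' programmatically: the Stomach reads the meal channel `NUT_INP` (to which
#' it also writes back its retention) and the feedback `IR_VE`; the
#' Intestine reads `NUT` (stomach output, optionally superimposed with an
#' ileal infusion attached as external data) and writes `IR_VA`; the CNS
#' closes the loop with `IR_VE` and additionally declares the unconsumed
#' `VAS` output.
#'
#' @param meal caloric value of the meal placed on `NUT_INP` at `t = 0`.
#' @param infusionTimes,infusionValues optional external infusion series for
#'   the `NUT` channel (native grid, min / caloric units per grid interval).
#' @param timeGrid header time grid of the emitted table (min).
#' @return a [ModelSpecTable-class].
#' @examples
#' spec <- gastricModelSpec()
#' validateModelSpec(spec)$code
#' @export
gastricModelSpec <- function(meal = 35.6,
                             infusionTimes = numeric(0),
                             infusionValues = numeric(0),
                             timeGrid = seq(0, 240, by = 5)) {
  rows <- data.frame(
    component = c("Stomach", "Stomach", "Stomach", "Stomach",
                  "Intestine", "Intestine", "CNS", "CNS", "CNS"),
    connect = TRUE,
    port = c("NUT_INP", "IR_VE", "NUT", "NUT_INP",
             "NUT", "IR_VA", "IR_VA", "IR_VE", "VAS"),
    direction = c("input", "input", "output", "output",
                  "input", "output", "input", "output", "output"),
    stringsAsFactors = FALSE)
  data <- matrix(NA_real_, nrow(rows), length(timeGrid))
  data[1, match(0, timeGrid)] <- meal
  if (length(infusionTimes)) {
    idx <- match(infusionTimes, timeGrid)
    if (anyNA(idx))
      stop("infusion times must lie on the time grid")
    data[5, idx] <- infusionValues
  }
  modelSpecTable(rows, data, timeGrid)
}
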