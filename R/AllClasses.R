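#' @import methods
NULL

#' ModelSpecTable: parsed model specification and data file
#'
#' In-memory representation of the row-wise tabular model specification and
#' experimental data format. Each row declares one port (input or output) of
#' one component, a `Connect` flag, and an optional sparse data series on the
#' shared header time grid. A port name that appears as the output of one
#' component and the input of another denotes a connection between the two.
#'
#' @slot rows data.frame with columns `component` (character), `connect`
#'   (logical), `port` (character) and `direction` (`"input"` or `"output"`),
#'   one row per declared port, in file order.
#' @slot data numeric matrix, `nrow(rows)` x `length(timeGrid)`; `NA` encodes
#'   a blank cell (no experimental data), which is distinct from zero.
#' @slot timeGrid strictly increasing numeric vector of time points (min).
#'
#' @seealso [readModelSpec()], [writeModelSpec()], [validateModelSpec()],
#'   [buildModel()]
#' @exportClass ModelSpecTable
setClass("ModelSpecTable",
  slots = c(rows = "data.frame", data = "matrix", timeGrid = "numeric"))

setValidity("ModelSpecTable", function(object) {
  msg <- character(0)
  req <- c("component", "connect", "port", "direction")
  if (!all(req %in% names(object@rows)))
    msg <- c(msg, paste("rows must have columns", paste(req, collapse = ", ")))
  else {
    if (!all(object@rows$direction %in% c("input", "output")))
      msg <- c(msg, "direction must be 'input' or 'output'")
    out <- object@rows$port[object@rows$direction == "output"]
    if (anyDuplicated(out))
      msg <- c(msg, paste("duplicate output port name:",
                          paste(unique(out[duplicated(out)]), collapse = ", ")))
    if (nrow(object@rows) != nrow(object@data))
      msg <- c(msg, "data must have one row per port row")
  }
  if (length(object@timeGrid) != ncol(object@data))
    msg <- c(msg, "data must have one column per time point")
  if (length(object@timeGrid) > 1 && any(diff(object@timeGrid) <= 0))
    msg <- c(msg, "time grid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelSpecTable
#'
#' @param rows data.frame of port rows (see [ModelSpecTable-class]).
#' @param data numeric matrix of experimental data, `NA` for blanks. May be
#'   omitted for a structure-only table.
#' @param timeGrid numeric vector of time points (min).
#' @return A [ModelSpecTable-class] object.
#' @examples
#' spec <- toyModelSpec()
#' components(spec)
#' @export
modelSpecTable <- function(rows, data = NULL, timeGrid = numeric(0)) {
  rows$component <- as.character(rows$component)
  rows$port <- as.character(rows$port)
  rows$direction <- as.character(rows$direction)
  rows$connect <- as.logical(rows$connect)
  rownames(rows) <- NULL
  if (is.null(data))
    data <- matrix(NA_real_, nrow(rows), length(timeGrid))
  storage.mode(data) <- "double"
  dimnames(data) <- NULL
  new("ModelSpecTable", rows = rows, data = data, timeGrid = as.numeric(timeGrid))
}

#' @describeIn modelSpecTable Component names, in declaration order.
#' @param spec a `ModelSpecTable`.
#' @export
components <- function(spec) unique(spec@rows$component)

#' @describeIn modelSpecTable Port rows as a data.frame.
#' @export
portRows <- function(spec) spec@rows

#' @describeIn modelSpecTable The header time grid (min).
#' @export
timeGrid <- function(spec) spec@timeGrid

#' @describeIn modelSpecTable Experimental data matrix (ports x times).
#' @export
specData <- function(spec) {
  d <- spec@data
  dimnames(d) <- list(spec@rows$port, spec@timeGrid)
  d
}

setMethod("show", "ModelSpecTable", function(object) {
  cat("ModelSpecTable with", length(components(object)), "components,",
      nrow(object@rows), "port rows,", length(object@timeGrid),
      "time points\n")
  cat("  components:", paste(components(object), collapse = ", "), "\n")
  n <- sum(!is.na(object@data))
  cat("  non-missing data cells:", n, "\n")
})

#' NetworkModel: components bound to information channels
#'
#' A simulable network built by [buildModel()] from a [ModelSpecTable-class]
#' and a function registry. Every distinct port name maps to exactly one
#' information channel; external data from the specification file are
#' attached to the channels that carry them.
#'
#' @slot components list of component descriptors (name, active input and
#'   output ports, function key, activation window in cycles).
#' @slot channels character vector of channel names.
#' @slot externalData named list (per channel) of data.frames with columns
#'   `time` and `value`, on the native grid of the specification file.
#' @slot registry environment mapping function keys to component transfer
#'   functions (see [registerFunction()]).
#'
#' @seealso [buildModel()], [simulateNetwork()], [addComponent()],
#'   [removeComponent()]
#' @exportClass NetworkModel
setClass("NetworkModel",
  slots = c(components = "list", channels = "character",
            externalData = "list", registry = "environment"))

setMethod("show", "NetworkModel", function(object) {
  cat("NetworkModel:", length(object@components), "components,",
      length(object@channels), "channels\n")
  for (cmp in object@components) {
    win <- if (is.finite(cmp$activeUntil))
      sprintf(" [cycles %g..%g]", cmp$activeFrom, cmp$activeUntil)
    else if (cmp$activeFrom > 0) sprintf(" [from cycle %g]", cmp$activeFrom)
    else ""
    cat(sprintf("  %s: in(%s) -> out(%s)%s\n", cmp$name,
                paste(cmp$inputs, collapse = ","),
                paste(cmp$outputs, collapse = ","), win))
  }
  ext <- names(object@externalData)[vapply(object@externalData, nrow, 0L) > 0]
  if (length(ext)) cat("  external data on:", paste(ext, collapse = ", "), "\n")
})

#' SimulationResult: trajectories and event log of a simulation run
#'
#' @slot times numeric vector of time stamps (min), length cycles + 1.
#' @slot trajectories numeric matrix, one row per time stamp and one column
#'   per channel; row `t` holds the value each channel presents at time `t`
#'   (the producer's write for the cycle completed at `t`, plus any external
#'   data attached at `t`).
#' @slot events data.frame with columns `time`, `component`, `event`.
#' @slot finalStates named list of final component states.
#'
#' @seealso [simulateNetwork()], [tidyTrajectories()]
#' @exportClass SimulationResult
setClass("SimulationResult",
  slots = c(times = "numeric", trajectories = "matrix", events = "data.frame",
            finalStates = "list"))

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult:", length(object@times) - 1, "cycles,",
      ncol(object@trajectories), "channels,",
      nrow(object@events), "events\n")
  cat("  t =", object@times[1], "...", object@times[length(object@times)],
      "min\n")
})

#' @rdname SimulationResult-class
#' @param result a `SimulationResult`.
#' @return `trajectories()`: the time x channel matrix; `channelSeries()`:
#'   one channel as a named numeric vector; `simEvents()`: the event log;
#'   `tidyTrajectories()`: a long data.frame (time, channel, value).
#' @export
trajectories <- function(result) result@trajectories

#' @rdname SimulationResult-class
#' @param channel channel name.
#' @export
channelSeries <- function(result, channel) {
  if (!channel %in% colnames(result@trajectories))
    stop("unknown channel: ", channel)
  stats::setNames(result@trajectories[, channel], result@times)
}

#' @rdname SimulationResult-class
#' @export
simEvents <- function(result) result@events

#' @rdname SimulationResult-class
#' @export
tidyTrajectories <- function(result) {
  data.frame(
    time = rep(result@times, ncol(result@trajectories)),
    channel = rep(colnames(result@trajectories), each = length(result@times)),
    value = as.vector(result@trajectories),
    stringsAsFactors = FALSE)
}

#' BreathCurveFit: fitted 13C excretion curve
#'
#' Parameters of the excretion-curve model `y = a * t^b * exp(-c*t)` fitted
#' to pooled percentage-dose/h breath-test measurements, with goodness of
#' fit. Derived gastric-emptying summaries are available through
#' [thalfFromFit()] (gamma-median half-excretion time) and [tlagFromFit()]
#' (time of peak excretion).
#'
#' @slot a scale (percent dose/h).
#' @slot b shape exponent (dimensionless).
#' @slot c rate constant (1/min).
#' @slot rss residual sum of squares at the optimum.
#' @slot nPoints number of (t, y) points used.
#'
#' @exportClass BreathCurveFit
setClass("BreathCurveFit",
  slots = c(a = "numeric", b = "numeric", c = "numeric",
            rss = "numeric", nPoints = "integer"))

setValidity("BreathCurveFit", function(object) {
  if (object@a <= 0 || object@b <= 0 || object@c <= 0)
    "a, b and c must all be positive" else TRUE
})

setMethod("show", "BreathCurveFit", function(object) {
  cat(sprintf("BreathCurveFit: y = %.4g * t^%.4g * exp(-%.4g t)\n",
              object@a, object@b, object@c))
  cat(sprintf("  rss = %.4g over %d points; Thalf = %.2f min, TLag = %.2f min\n",
              object@rss, object@nPoints,
              thalfFromFit(object), tlagFromFit(object)))
})

#' @rdname BreathCurveFit-class
#' @param fit a `BreathCurveFit`.
#' @return `curveCoef()`: named numeric vector `c(a=, b=, c=)`.
#' @export
curveCoef <- function(fit) c(a = fit@a, b = fit@b, c = fit@c)

#' GastricScenario: result of a forward gastric-emptying simulation
#'
#' @slot thalf simulated half-emptying time (min), linearly interpolated from
#'   the stomach retention trajectory; `NA` if the stomach content never
#'   crosses half the meal within the horizon.
#' @slot tlag lag time reported for the scenario (min). The retention model
#'   carries its lag in the shape parameter `b = exp(k*T_LAG)`, so the lag is
#'   the `T_LAG` parameter itself and is not re-estimated per scenario.
#' @slot retention data.frame (`time`, `retained`) of stomach content.
#' @slot brakeEvents data.frame of logged brake events (time, component,
#'   event).
#' @slot result the full [SimulationResult-class].
#'
#' @seealso [runScenario()]
#' @exportClass GastricScenario
setClass("GastricScenario",
  slots = c(thalf = "numeric", tlag = "numeric", retention = "data.frame",
            brakeEvents = "data.frame", result = "SimulationResult"))

setMethod("show", "GastricScenario", function(object) {
  cat("GastricScenario:\n")
  cat(sprintf("  Thalf = %s min, TLag = %.2f min, %d brake events\n",
              if (is.na(object@thalf)) "not reached" else
                sprintf("%.2f", object@thalf),
              object@tlag, nrow(object@brakeEvents)))
})

#' @rdname GastricScenario-class
#' @param scenario a `GastricScenario`.
#' @export
scenarioThalf <- function(scenario) scenario@thalf

#' @rdname GastricScenario-class
#' @export
scenarioTlag <- function(scenario) scenario@tlag

#' @rdname GastricScenario-class
#' @export
retentionCurve <- function(scenario) scenario@retention

#' @rdname GastricScenario-class
#' @export
brakeEvents <- function(scenario) scenario@brakeEvents
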