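#' Component function registry
#'
#' The simulator resolves each component's behaviour through a registry that
#' maps a key (usually the component name) to a transfer function. A
#' transfer function has the contract
#'
#' ```
#' function(inputs, state, time, dt)
#' ```
#'
#' where `inputs` is a named numeric vector holding the values presented on
#' the component's connected input channels at the current cycle, `state` is
#' the component's opaque state (`NULL` on the first cycle), `time` is the
#' stamp of the cycle being completed (min) and `dt` the cycle length (min).
#' It must return `list(outputs = <named numeric>, state = <new state>)`,
#' naming every connected output port; an optional `events` element
#' (character vector) is appended to the simulation event log.
#'
#' @param registry an environment created by `functionRegistry()`.
#' @param key nonempty character key.
#' @param fn transfer function with the contract above.
#' @return `functionRegistry()`: a new empty registry.
#'   `registerFunction()`: the registry, invisibly. Re-registering an
#'   existing key overwrites it with a warning.
#' @examples
#' reg <- functionRegistry()
#' registerFunction(reg, "relay", function(inputs, state, time, dt)
#'   list(outputs = c(B = unname(inputs["A"])), state = state))
#' registryKeys(reg)
#' @export
functionRegistry <- function() new.env(parent = emptyenv())

#' @rdname functionRegistry
#' @export
registerFunction <- function(registry, key, fn) {
  stopifnot(is.environment(registry))
  if (!is.character(key) || length(key) != 1 || !nzchar(key))
    stop("key must be a nonempty string")
  if (!is.function(fn)) stop("fn must be a function")
  if (exists(key, envir = registry, inherits = FALSE))
    warning("overwriting registered function '", key, "'")
  assign(key, fn, envir = registry)
  invisible(registry)
}

#' @rdname functionRegistry
#' @export
registryKeys <- function(registry) sort(ls(registry))

#' Build a network model from a specification table
#'
#' Binds every distinct port name to one information channel, attaches the
#' specification file's external data (cells on input-port rows) to the
#' channels that carry them, and resolves every component name in the
#' function registry. Ports with `Connect = No` are excluded from the
#' component's active port sets. If the same input port carries data on
#' several rows, the series are summed.
#'
#' @param spec a [ModelSpecTable-class].
#' @param registry a function registry (see [registerFunction()]) resolving
#'   every component name in `spec`.
#' @return A [NetworkModel-class].
#' @examples
#' toy <- makeToyNetwork()
#' model <- buildModel(toy$spec, toy$registry)
#' model
#' @export
buildModel <- function(spec, registry) {
  stopifnot(is(spec, "ModelSpecTable"), is.environment(registry))
  validObject(spec)
  comps <- components(spec)
  missing <- setdiff(comps, ls(registry))
  if (length(missing))
    stop("no registered function for component(s): ",
         paste(missing, collapse = ", "))
  rows <- spec@rows
  channels <- unique(rows$port)
  writers <- rows$component[rows$connect & rows$direction == "output"]
  wports <- rows$port[rows$connect & rows$direction == "output"]
  if (anyDuplicated(wports))
    stop("duplicate writer to channel(s): ",
         paste(unique(wports[duplicated(wports)]), collapse = ", "))
  componentList <- lapply(comps, function(cn) {
    r <- rows[rows$component == cn & rows$connect, , drop = FALSE]
    list(name = cn,
         inputs = r$port[r$direction == "input"],
         outputs = r$port[r$direction == "output"],
         functionKey = cn,
         activeFrom = 0, activeUntil = Inf)
  })
  external <- stats::setNames(
    lapply(channels, function(ch) {
      idx <- which(rows$port == ch & rows$direction == "input")
      tt <- spec@timeGrid
      v <- if (length(idx))
        colSums(matrix(spec@data[idx, , drop = FALSE], nrow = length(idx)),
                na.rm = TRUE) * ifelse(
                  colSums(!is.na(spec@data[idx, , drop = FALSE])) > 0, 1, NA)
      else rep(NA_real_, length(tt))
      keep <- !is.na(v)
      data.frame(time = tt[keep], value = v[keep])
    }), channels)
  new("NetworkModel", components = componentList, channels = channels,
      externalData = external, registry = registry)
}

#' Attach or replace an external data series on a channel
#'
#' External data represent measured or supplied values on an information
#' channel. During simulation the series is superimposed on (added to)
#' whatever the producing component wrote in the previous cycle. A series on
#' a grid coarser than the simulation step is interpreted as an amount
#' delivered over each grid interval and is spread uniformly across the
#' cycles within it.
#'
#' @param model a [NetworkModel-class].
#' @param channel channel name.
#' @param time,value numeric vectors (native grid, min).
#' @return the modified model.
#' @export
setExternalData <- function(model, channel, time, value) {
  stopifnot(is(model, "NetworkModel"), length(time) == length(value))
  if (!channel %in% model@channels)
    model@channels <- c(model@channels, channel)
  o <- order(time)
  model@externalData[[channel]] <- data.frame(time = time[o], value = value[o])
  model
}

#' Add or remove a component at a cycle boundary
#'
#' Structural edits take effect at completed cycle boundaries, so the past
#' trajectory of a run is unchanged by an edit scheduled at a later cycle.
#' Removing a channel's sole writer leaves the channel at its external data
#' (or zero). Adding a second simultaneous writer to a channel is an error.
#'
#' @param model a [NetworkModel-class].
#' @param name component name.
#' @param inputs,outputs character vectors of port names.
#' @param functionKey registry key resolving the component's transfer
#'   function (defaults to `name`).
#' @param atCycle first cycle (counted from the start of the next
#'   simulation) at which the component is active / inactive.
#' @return the modified model.
#' @examples
#' toy <- makeToyNetwork()
#' model <- buildModel(toy$spec, toy$registry)
#' model2 <- removeComponent(model, "C3", atCycle = 4)
#' @export
addComponent <- function(model, name, inputs, outputs,
                         functionKey = name, atCycle = 0) {
  stopifnot(is(model, "NetworkModel"))
  if (!exists(functionKey, envir = model@registry, inherits = FALSE))
    stop("no registered function for key: ", functionKey)
  for (cmp in model@components) {
    clash <- intersect(outputs, cmp$outputs)
    if (length(clash) && cmp$activeUntil > atCycle)
      stop("duplicate writer to channel(s): ", paste(clash, collapse = ", "))
  }
  model@components <- c(model@components, list(list(
    name = name, inputs = inputs, outputs = outputs,
    functionKey = functionKey, activeFrom = atCycle, activeUntil = Inf)))
  newCh <- setdiff(c(inputs, outputs), model@channels)
  model@channels <- c(model@channels, newCh)
  for (ch in newCh)
    model@externalData[[ch]] <- data.frame(time = numeric(0),
                                           value = numeric(0))
  model
}

#' @rdname addComponent
#' @export
removeComponent <- function(model, name, atCycle = 0) {
  stopifnot(is(model, "NetworkModel"))
  idx <- which(vapply(model@components, `[[`, "", "name") == name)
  if (!length(idx)) stop("unknown component: ", name)
  for (i in idx) model@components[[i]]$activeUntil <- atCycle
  model
}

#' Simulate a network model cycle by cycle
#'
#' Runs `(tEnd - tStart)/dt` simulation cycles. At the cycle completed at
#' time `t`, every active component reads the values its connected input
#' channels presented at `t - dt` -- the producer's write from the previous
#' cycle plus any external data attached there -- and writes its outputs,
#' which the channels present at `t`. A cycle is complete once every active
#' component's outputs have been evaluated; reads always precede all writes
#' of the cycle, so the result does not depend on evaluation order and
#' cyclic wiring needs no algebraic-loop solving. Channels written by no
#' active component present their external data, or zero.
#'
#' @param model a [NetworkModel-class].
#' @param tStart,tEnd simulation window (min).
#' @param dt cycle length (min); `(tEnd - tStart)/dt` must be integral.
#' @return A [SimulationResult-class] whose trajectory matrix has one row
#'   per time stamp `tStart, tStart + dt, ..., tEnd` and one column per
#'   channel.
#' @examples
#' toy <- makeToyNetwork()
#' model <- buildModel(toy$spec, toy$registry)
#' res <- simulateNetwork(model, tEnd = 35, dt = 5)
#' channelSeries(res, "B")
#' @export
setGeneric("simulateNetwork", function(model, tStart = 0, tEnd = 240, dt = 1)
  standardGeneric("simulateNetwork"))

#' @rdname simulateNetwork
#' @export
setMethod("simulateNetwork", "NetworkModel",
          function(model, tStart = 0, tEnd = 240, dt = 1) {
  if (dt <= 0) stop("dt must be > 0")
  ncyc <- (tEnd - tStart) / dt
  if (abs(ncyc - round(ncyc)) > 1e-9)
    stop("(tEnd - tStart)/dt must be an integral number of cycles")
  ncyc <- as.integer(round(ncyc))
  times <- tStart + dt * (0:ncyc)
  channels <- model@channels
  ext <- externalPerCycle(model, times, dt)
  traj <- matrix(0, ncyc + 1, length(channels),
                 dimnames = list(NULL, channels))
  traj[1, ] <- ext[1, ]
  lastWrite <- stats::setNames(numeric(length(channels)), channels)
  states <- stats::setNames(vector("list", length(model@components)),
                            vapply(model@components, `[[`, "", "name"))
  events <- list()
  for (i in seq_len(ncyc)) {
    t <- times[i + 1]
    presented <- lastWrite + ext[i, ]
    writes <- stats::setNames(numeric(length(channels)), channels)
    for (ci in seq_along(model@components)) {
      cmp <- model@components[[ci]]
      if (i - 1 < cmp$activeFrom || i - 1 >= cmp$activeUntil) next
      fn <- get(cmp$functionKey, envir = model@registry, inherits = FALSE)
      res <- tryCatch(
        fn(presented[cmp$inputs], states[[ci]], t, dt),
        error = function(e) stop("component '", cmp$name, "' failed at t = ",
                                 t, " (cycle ", i, "): ", conditionMessage(e),
                                 call. = FALSE))
      if (!is.list(res) || !all(c("outputs", "state") %in% names(res)))
        stop("component '", cmp$name,
             "' violated the transfer-function contract (cycle ", i, ")")
      out <- res$outputs
      if (!all(cmp$outputs %in% names(out)))
        stop("component '", cmp$name, "' did not write output(s): ",
             paste(setdiff(cmp$outputs, names(out)), collapse = ", "))
      out <- out[cmp$outputs]
      if (any(!is.finite(out)))
        stop("component '", cmp$name, "' wrote a non-finite value at t = ",
             t, " (cycle ", i, ")")
      writes[cmp$outputs] <- out
      states[ci] <- list(res$state)   # keep NULL states without shrinking
      for (ev in res$events)
        events[[length(events) + 1]] <-
          data.frame(time = t, component = cmp$name, event = ev,
                     stringsAsFactors = FALSE)
    }
    lastWrite <- writes
    traj[i + 1, ] <- writes + ext[i + 1, ]
  }
  new("SimulationResult", times = times, trajectories = traj,
      events = if (length(events)) do.call(rbind, events)
               else data.frame(time = numeric(0), component = character(0),
                               event = character(0), stringsAsFactors = FALSE),
      finalStates = states)
})

# Per-cycle external contribution matrix (times x channels). A value on a
# native grid interval wider than dt is an amount delivered over that
# interval, spread uniformly over the dt-cycles starting within it.
externalPerCycle <- function(model, times, dt) {
  out <- matrix(0, length(times), length(model@channels),
                dimnames = list(NULL, model@channels))
  for (ch in names(model@externalData)) {
    ed <- model@externalData[[ch]]
    if (!nrow(ed)) next
    widths <- if (nrow(ed) > 1) diff(ed$time) else dt
    widths <- c(widths, widths[length(widths)])
    for (j in seq_len(nrow(ed))) {
      w <- widths[j]
      if (w <= dt + 1e-9) {
        k <- which(abs(times - ed$time[j]) < dt / 2 - 1e-9 |
                     abs(times - ed$time[j]) < 1e-9)
        if (length(k)) out[k[1], ch] <- out[k[1], ch] + ed$value[j]
      } else {
        k <- which(times >= ed$time[j] - 1e-9 &
                     times < ed$time[j] + w - 1e-9)
        if (length(k))
          out[k, ch] <- out[k, ch] + ed$value[j] * dt / w
      }
    }
  }
  out
}

#' Export a simulation result to delimited text
#'
#' Writes the trajectories in tidy long form (`time, channel, value`) and,
#' optionally, the event log (`time, component, event`).
#'
#' @param result a [SimulationResult-class].
#' @param path output CSV path for the trajectories.
#' @param eventsPath optional output CSV path for the event log.
#' @return `path`, invisibly.
#' @export
writeSimulationResult <- function(result, path, eventsPath = NULL) {
  utils::write.csv(tidyTrajectories(result), path, row.names = FALSE)
  if (!is.null(eventsPath))
    utils::write.csv(simEvents(result), eventsPath, row.names = FALSE)
  invisible(path)
}
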