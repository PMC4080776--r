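#' Read a model specification and data file
#'
#' Parses the row-wise tabular format: a header row
#' `Components, Connect, Inputs, Outputs` followed by numeric time columns,
#' then one row per port. A row with a name in the `Inputs` column (and a
#' blank `Outputs` cell) declares an input port, and vice versa. A blank
#' `Components` cell continues the component declared above it. Blank data
#' cells mean "no experimental data" and are parsed as `NA`, which is
#' distinct from an explicit `0`.
#'
#' @param path path to a delimited text file. The delimiter (comma or tab)
#'   is auto-detected from the header row unless given.
#' @param delimiter optional delimiter override (`","` or `"\t"`).
#' @return A [ModelSpecTable-class].
#' @examples
#' path <- system.file("extdata", "toy_network.csv", package = "gastroSim")
#' spec <- readModelSpec(path)
#' spec
#' @seealso [writeModelSpec()], [validateModelSpec()]
#' @export
readModelSpec <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("malformed header: empty file")
  if (is.null(delimiter))
    delimiter <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  split1 <- function(x) trimws(strsplit(x, delimiter, fixed = TRUE)[[1]])
  header <- split1(lines[1])
  need <- c("Components", "Connect", "Inputs", "Outputs")
  if (length(header) < 4 || !all(tolower(header[1:4]) == tolower(need)))
    stop("malformed header: expected columns ",
         paste(need, collapse = ", "), " followed by time points")
  grid <- suppressWarnings(as.numeric(header[-(1:4)]))
  if (anyNA(grid))
    stop("malformed header: non-numeric time column ",
         paste(header[-(1:4)][is.na(grid)], collapse = ", "))
  nT <- length(grid)
  rows <- list(); dat <- list(); lastComp <- ""
  for (i in seq_along(lines)[-1]) {
    f <- split1(lines[i])
    length(f) <- 4 + nT                 # pad short rows with NA
    f[is.na(f)] <- ""
    comp <- f[1]
    if (!nzchar(comp)) comp <- lastComp
    if (!nzchar(comp))
      stop("row ", i - 1, ": missing component name")
    lastComp <- comp
    connect <- tolower(f[2])
    if (!connect %in% c("yes", "no"))
      stop("row ", i - 1, ": Connect must be Yes or No, got '", f[2], "'")
    hasIn <- nzchar(f[3]); hasOut <- nzchar(f[4])
    if (hasIn == hasOut)
      stop("row ", i - 1, ": exactly one of Inputs/Outputs must be named")
    vals <- rep(NA_real_, nT)
    cells <- f[4 + seq_len(nT)]
    filled <- nzchar(cells)
    if (any(filled)) {
      v <- suppressWarnings(as.numeric(cells[filled]))
      if (anyNA(v)) {
        bad <- which(filled)[is.na(v)][1]
        stop("row ", i - 1, ", time column ", grid[bad],
             ": non-numeric data cell '", cells[bad], "'")
      }
      vals[filled] <- v
    }
    rows[[length(rows) + 1]] <- data.frame(
      component = comp, connect = connect == "yes",
      port = if (hasIn) f[3] else f[4],
      direction = if (hasIn) "input" else "output",
      stringsAsFactors = FALSE)
    dat[[length(dat) + 1]] <- vals
  }
  if (!length(rows)) stop("no port rows found")
  modelSpecTable(do.call(rbind, rows),
                 do.call(rbind, dat), grid)
}

#' Write a model specification and data file
#'
#' Inverse of [readModelSpec()]: `readModelSpec(writeModelSpec(spec, path))`
#' reproduces `spec` exactly, including blank (missing) cells, which are
#' never written as zeros.
#'
#' @param spec a [ModelSpecTable-class].
#' @param path output file path.
#' @param delimiter field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
writeModelSpec <- function(spec, path, delimiter = ",") {
  stopifnot(is(spec, "ModelSpecTable"))
  validObject(spec)
  fmt <- function(x) ifelse(is.na(x), "", vapply(x, function(v)
    format(v, digits = 15, scientific = FALSE, trim = TRUE), ""))
  header <- c("Components", "Connect", "Inputs", "Outputs",
              fmt(spec@timeGrid))
  rows <- spec@rows
  prev <- ""
  out <- vapply(seq_len(nrow(rows)), function(i) {
    comp <- if (rows$component[i] == prev) "" else rows$component[i]
    prev <<- rows$component[i]
    paste(c(comp,
            if (rows$connect[i]) "Yes" else "No",
            if (rows$direction[i] == "input") rows$port[i] else "",
            if (rows$direction[i] == "output") rows$port[i] else "",
            fmt(spec@data[i, ])), collapse = delimiter)
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = delimiter), out), con)
  invisible(path)
}

#' Diagnose a model specification
#'
#' Static checks on the wiring of a [ModelSpecTable-class]. Reports, without
#' ever modifying the specification:
#' \itemize{
#'   \item inputs fed by no output and carrying no external data (the
#'     channel will read as 0 every cycle) -- warning;
#'   \item outputs consumed by no input (allowed; the value is simply
#'     recorded) -- warning;
#'   \item `Connect = No` rows -- informational;
#'   \item feedback loops, including self-loops, which the simulator
#'     resolves with a one-cycle delay rather than algebraically.
#' }
#'
#' @param spec a [ModelSpecTable-class].
#' @return data.frame with columns `severity` (`"info"`/`"warning"`),
#'   `code` and `message`; zero rows if nothing to report.
#' @examples
#' diag <- validateModelSpec(gastricModelSpec())
#' diag[, c("severity", "code")]
#' @export
validateModelSpec <- function(spec) {
  stopifnot(is(spec, "ModelSpecTable"))
  validObject(spec)
  rows <- spec@rows
  hasData <- rowSums(!is.na(spec@data)) > 0
  act <- rows[rows$connect, , drop = FALSE]
  outPorts <- act$port[act$direction == "output"]
  inPorts <- act$port[act$direction == "input"]
  d <- list()
  note <- function(severity, code, message)
    d[[length(d) + 1]] <<- data.frame(severity = severity, code = code,
                                      message = message,
                                      stringsAsFactors = FALSE)
  for (i in which(rows$connect & rows$direction == "input")) {
    if (!(rows$port[i] %in% outPorts) && !hasData[i])
      note("warning", "unfed_input",
           sprintf("input %s of %s has no producing output and no external data; channel defaults to 0",
                   rows$port[i], rows$component[i]))
  }
  for (i in which(rows$connect & rows$direction == "output")) {
    if (!(rows$port[i] %in% inPorts))
      note("warning", "unconsumed_output",
           sprintf("output %s of %s is consumed by no component",
                   rows$port[i], rows$component[i]))
  }
  for (i in which(!rows$connect))
    note("info", "disconnected",
         sprintf("%s port %s of %s has Connect=No and is skipped at %s time",
                 rows$direction[i], rows$port[i], rows$component[i],
                 if (rows$direction[i] == "input") "read" else "write"))
  loops <- specFeedbackLoops(spec)
  for (lp in loops)
    note(if (length(lp) == 1) "warning" else "info", "feedback_loop",
         sprintf("feedback loop through %s is resolved with a one-cycle delay",
                 paste(lp, collapse = " -> ")))
  if (length(d)) do.call(rbind, d)
  else data.frame(severity = character(0), code = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

# Components lying on feedback loops, grouped per loop-carrying component set.
# Boolean reachability on the (small) component graph; an edge runs from the
# producer of a connected output port to every component reading that port.
specFeedbackLoops <- function(spec) {
  rows <- spec@rows[spec@rows$connect, , drop = FALSE]
  comps <- unique(spec@rows$component)
  n <- length(comps)
  adj <- matrix(FALSE, n, n, dimnames = list(comps, comps))
  for (i in which(rows$direction == "output")) {
    readers <- rows$component[rows$direction == "input" &
                                rows$port == rows$port[i]]
    adj[rows$component[i], readers] <- TRUE
  }
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ]) > 0
  inLoop <- diag(reach)
  if (!any(inLoop)) return(list())
  # group mutually reachable loop members into one reported loop each
  members <- comps[inLoop]
  groups <- list()
  seen <- character(0)
  for (m in members) {
    if (m %in% seen) next
    grp <- members[reach[m, members] & reach[members, m]]
    if (!length(grp)) grp <- m
    seen <- c(seen, grp)
    groups[[length(groups) + 1]] <- grp
  }
  groups
}
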