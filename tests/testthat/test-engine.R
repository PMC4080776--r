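# Model building and cycle-by-cycle simulation over information channels.

test_that("registering component functions resolves, overwrites with warning", {
  toy <- makeToyNetwork()
  expect_s4_class(buildModel(toy$spec, toy$registry), "NetworkModel")

  reg <- functionRegistry()
  registerFunction(reg, "CNS", function(inputs, state, time, dt)
    list(outputs = c(IR_VE = 0), state = state))
  expect_warning(registerFunction(reg, "CNS", function(inputs, state, time, dt)
    list(outputs = c(IR_VE = 1), state = state)), "overwriting")

  # building against a registry missing components names them all
  expect_error(buildModel(gastricModelSpec(), reg),
               "Stomach.*Intestine|no registered function")
})

test_that("a pulse propagates with exactly one cycle of delay per hop", {
  # hand-trace of the example network (sum functions, dt = one grid step):
  # cycle 1: C1 reads A=20 -> B; cycle 2: C2 and C3 read B -> C, D;
  # cycle 3: D feeds back into C1 -> B again, while B=0 gives C=D=0.
  toy <- makeToyNetwork()
  res <- simulateNetwork(buildModel(toy$spec, toy$registry),
                         tEnd = 35, dt = 5)
  tr <- trajectories(res)
  expect_equal(unname(tr[, "B"][1:4]), c(0, 20, 0, 20))
  expect_equal(unname(tr[, "C"][1:4]), c(0, 0, 20, 0))
  expect_equal(unname(tr[, "D"][1:4]), c(0, 0, 20, 0))

  # property: for a pure pass-through chain of n components, the pulse
  # reaches the last output exactly at cycle n
  for (n in c(2, 5)) {
    chain <- makeRelayChain(n)
    res <- simulateNetwork(buildModel(chain$spec, chain$registry),
                           tEnd = n + 2, dt = 1)
    lastOut <- trajectories(res)[, paste0("s", n)]
    expect_equal(which(lastOut != 0) - 1, n)   # row n+1 <=> cycle n
    expect_equal(unname(lastOut[n + 1]), 1)
  }
})

test_that("zero dynamics stay zero and runs are deterministic", {
  toy <- makeToyNetwork()
  reg <- functionRegistry()
  zero <- function(out) function(inputs, state, time, dt)
    list(outputs = stats::setNames(0, out), state = state)
  registerFunction(reg, "C1", zero("B"))
  registerFunction(reg, "C2", zero("C"))
  registerFunction(reg, "C3", zero("D"))
  spec <- toy$spec
  spec@data[] <- NA_real_   # no external pulse either
  res <- simulateNetwork(buildModel(spec, reg), tEnd = 35, dt = 5)
  expect_true(all(trajectories(res) == 0))

  m <- buildModel(toy$spec, toy$registry)
  r1 <- simulateNetwork(m, tEnd = 35, dt = 5)
  r2 <- simulateNetwork(m, tEnd = 35, dt = 5)
  expect_identical(trajectories(r1), trajectories(r2))
})

test_that("each channel accepts a single writer", {
  toy <- makeToyNetwork()
  m <- buildModel(toy$spec, toy$registry)
  expect_error(addComponent(m, "C4", inputs = "A", outputs = "B",
                            functionKey = "C1"),
               "duplicate writer")
})

test_that("with a zero-function writer a channel reproduces its external data", {
  rows <- data.frame(component = "W", connect = TRUE, port = c("u", "v"),
                     direction = c("input", "output"),
                     stringsAsFactors = FALSE)
  grid <- seq(0, 6)
  data <- matrix(NA_real_, 2, length(grid))
  data[1, ] <- c(0, 1, 4, 9, 16, 25, 36)
  spec <- modelSpecTable(rows, data, grid)
  reg <- functionRegistry()
  registerFunction(reg, "W", function(inputs, state, time, dt)
    list(outputs = c(v = 0), state = state))
  res <- simulateNetwork(buildModel(spec, reg), tEnd = 6, dt = 1)
  expect_equal(unname(channelSeries(res, "u")), data[1, ])
})

test_that("external data on a coarse grid is spread across internal cycles", {
  rows <- data.frame(component = "W", connect = TRUE, port = c("u", "v"),
                     direction = c("input", "output"),
                     stringsAsFactors = FALSE)
  data <- matrix(c(0.5, 0.5, NA, NA), 2, 2, byrow = TRUE)
  spec <- modelSpecTable(rows, data, timeGrid = c(0, 5))
  reg <- functionRegistry()
  registerFunction(reg, "W", function(inputs, state, time, dt)
    list(outputs = c(v = 0), state = state))
  res <- simulateNetwork(buildModel(spec, reg), tEnd = 10, dt = 1)
  u <- unname(channelSeries(res, "u"))
  # 0.5 per 5-min column -> 0.1 per 1-min cycle over each column's interval
  expect_equal(u, c(rep(0.1, 10), 0))
})

test_that("structural edits at cycle boundaries leave the past unchanged", {
  toy <- makeToyNetwork()
  m <- buildModel(toy$spec, toy$registry)
  full <- simulateNetwork(m, tEnd = 35, dt = 5)
  cut <- simulateNetwork(removeComponent(m, "C3", atCycle = 4),
                         tEnd = 35, dt = 5)
  # cycles 0..3 (rows 1..4, stamped completion of cycle 4 not included)
  expect_identical(trajectories(full)[1:4, ], trajectories(cut)[1:4, ])
  # after removal the D channel has no writer and reads 0
  expect_true(all(trajectories(cut)[6:8, "D"] == 0))
  expect_error(removeComponent(m, "nope"), "unknown component")

  # a pass-through component added mid-run makes its downstream channel
  # nonzero one cycle after activation
  reg <- functionRegistry()
  registerFunction(reg, "relay", function(inputs, state, time, dt)
    list(outputs = c(w = sum(inputs)), state = state))
  rows <- data.frame(component = "Src", connect = TRUE, port = c("z", "u"),
                     direction = c("input", "output"),
                     stringsAsFactors = FALSE)
  spec <- modelSpecTable(rows, timeGrid = 0:8)
  regSrc <- functionRegistry()
  registerFunction(regSrc, "Src", function(inputs, state, time, dt)
    list(outputs = c(u = 1), state = state))
  registerFunction(regSrc, "relay", get("relay", envir = reg))
  m2 <- addComponent(buildModel(spec, regSrc), "Tap",
                     inputs = "u", outputs = "w",
                     functionKey = "relay", atCycle = 3)
  res <- simulateNetwork(m2, tEnd = 8, dt = 1)
  w <- unname(channelSeries(res, "w"))
  expect_true(all(w[1:4] == 0))       # inactive through cycle 3's start
  expect_true(all(w[5:9] == 1))       # first write at cycle 4
})

test_that("misbehaving component functions abort with component and cycle", {
  rows <- data.frame(component = "Bad", connect = TRUE, port = c("p", "q"),
                     direction = c("input", "output"),
                     stringsAsFactors = FALSE)
  spec <- modelSpecTable(rows, timeGrid = 0:3)
  reg <- functionRegistry()
  registerFunction(reg, "Bad", function(inputs, state, time, dt)
    list(outputs = c(q = NaN), state = state))
  expect_error(simulateNetwork(buildModel(spec, reg), tEnd = 3, dt = 1),
               "'Bad' wrote a non-finite value")
  suppressWarnings(
    registerFunction(reg, "Bad", function(inputs, state, time, dt) 42))
  expect_error(simulateNetwork(buildModel(spec, reg), tEnd = 3, dt = 1),
               "transfer-function contract")
  suppressWarnings(registerFunction(reg, "Bad",
    function(inputs, state, time, dt) stop("boom")))
  expect_error(simulateNetwork(buildModel(spec, reg), tEnd = 3, dt = 1),
               "component 'Bad' failed at t = 1 \\(cycle 1\\)")
})

test_that("trajectories cover every channel at every cycle and export tidily", {
  toy <- makeToyNetwork()
  res <- simulateNetwork(buildModel(toy$spec, toy$registry), tEnd = 35, dt = 5)
  expect_equal(dim(trajectories(res)), c(8, 4))
  tidy <- tidyTrajectories(res)
  expect_identical(names(tidy), c("time", "channel", "value"))
  expect_equal(nrow(tidy), 8 * 4)
  f <- tempfile(fileext = ".csv")
  writeSimulationResult(res, f)
  expect_equal(nrow(utils::read.csv(f)), 32)
})
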