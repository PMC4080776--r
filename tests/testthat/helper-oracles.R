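# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths: quadrature + root bracketing instead of
# the inverse incomplete gamma, dense grid search instead of the closed-form
# argmax, and the analytic retention curve instead of the cycle simulator.

# half-excretion time of y = t^b exp(-c t) by adaptive quadrature + uniroot
thalfQuadratureOracle <- function(b, c) {
  f <- function(t) t^b * exp(-c * t)
  total <- stats::integrate(f, 0, Inf, rel.tol = 1e-12)$value
  g <- function(x) stats::integrate(f, 0, x, rel.tol = 1e-12)$value - total / 2
  stats::uniroot(g, c(1e-6, 50 / c), tol = 1e-9)$root
}

# argmax of t^b exp(-c t) by dense grid search
tlagGridOracle <- function(b, c, resolution = 0.01) {
  tt <- seq(resolution, 5 * b / c, by = resolution)
  tt[which.max(tt^b * exp(-c * tt))]
}

# no-feedback half-emptying time of the retention curve, by root finding
thalfRetentionOracle <- function(k, T_LAG) {
  b <- exp(k * T_LAG)
  stats::uniroot(function(t) (1 - (1 - exp(-k * t))^b) - 0.5,
                 c(1e-6, 1e5 / (k * 1e2)), tol = 1e-10)$root
}

# chain of n pass-through relay components In -> s1 -> ... -> sn
makeRelayChain <- function(n) {
  ports <- c("In", paste0("s", seq_len(n)))
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(component = paste0("R", i), connect = TRUE,
               port = ports[c(i, i + 1)],
               direction = c("input", "output"),
               stringsAsFactors = FALSE)))
  grid <- seq(0, n + 2)
  data <- matrix(NA_real_, nrow(rows), length(grid))
  data[1, 1] <- 1   # unit pulse on In at t = 0
  spec <- modelSpecTable(rows, data, grid)
  reg <- functionRegistry()
  for (i in seq_len(n)) {
    out <- ports[i + 1]
    registerFunction(reg, paste0("R", i), local({
      o <- out
      function(inputs, state, time, dt)
        list(outputs = stats::setNames(sum(inputs), o), state = state)
    }))
  }
  list(spec = spec, registry = reg)
}

referenceParams <- function(brakeless = FALSE)
  list(stomach = stomachParams(k = 0.009, T_LAG = 91.72, THD = 0.45,
                               IR_TR = 0.3, BRK = 0.03, CAL_GRD = 0.6),
       intestine = intestineParams(INV_DR = 0.1, T_MAX = 10),
       cns = cnsParams(TRF_K = if (brakeless) 0 else 1))

safflowerInfusion <- function() list(rate = 0.5, per = 5, start = 30, end = 120)

# single-start grid keeps repeated fits cheap in property loops
fastStart <- list(a = 0.3, b = 1, c = 0.01)
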