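## shared fixtures, built in code

## calibrated reference parameter set, computed once per session
refParams <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrateReference()
    cache
  }
})

gateLabels <- function(path) sub("\\..*$", "", path@states)

## per-frame generating labels of a rendered trace
truthLabels <- function(path, trace) {
  g <- gateLabels(path)[findInterval(trace@time, path@entryTime)]
  ifelse(g == "OPEN", "OPEN", "CLOSED")
}

makePath <- function(states, entry, duration, mg = 3, seed = 1L) {
  new("StatePath", states = states, entryTime = entry, duration = duration,
      mg = mg, seed = as.integer(seed))
}

## alternating gate path with prescribed macro-dwell durations (s)
alternatingPath <- function(durations, mg = 3) {
  states <- rep(c("CLOSED.B_CC", "OPEN.B_OC"),
                length.out = length(durations))
  makePath(states, cumsum(c(0, durations[-length(durations)])),
           sum(durations), mg = mg)
}

## idealized path from explicit run lengths (frames at `rate` Hz)
pathFromRuns <- function(run_frames, rate = 1,
                         first = "CLOSED") {
  lab <- rep(rep(c(first, setdiff(c("CLOSED", "OPEN"), first)),
                 length.out = length(run_frames)), run_frames)
  new("IdealizedPath", labels = lab,
      levels = c(CLOSED = 0, OPEN = 6), noiseSd = 0, rate = rate,
      method = "threshold")
}

## delta-method standard error of 1/mean(x)
rateSE <- function(x) stats::sd(x) / (mean(x)^2 * sqrt(length(x)))
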