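## The salt-bridge-switch kinetic model.
##
## Mechanism: the gate (CLOSED/OPEN) is coupled to the salt-bridge
## configuration of the acidic triad.  The interdomain bridge (B_CC) latches
## the gate closed; the intradomain bridge (B_OC) licenses opening.  Mg2+
## catalyzes bridge disruption (B_* -> [E+Mg]) and also sequesters the apo
## state (APO -> [E+Mg]), so switching is breaking-limited at low Mg and
## formation-limited at high Mg -- the biphasic optimum.

#' Build a kinetic scheme for a variant
#'
#' Assembles the 8-state salt-bridge-switch scheme for a given parameter set
#' and enzyme variant.  Variant modifiers: `"2E2Q"` (E454Q/E457Q) removes the
#' triad Mg2+ site and the interdomain bridge (`k_on = k_cat = k_form_CC = 0`);
#' `"R447G"` scales the intradomain bridge-formation rate `k_form_OC` by
#' `r447gScale`; `"WT"` and `"custom"` leave the parameters untouched.
#'
#' @param params a [RateParameters-class] object.
#' @param variant `"WT"`, `"2E2Q"`, `"R447G"` or `"custom"`.
#' @param r447gScale multiplier on `k_form_OC` for the R447G variant
#'   (default 0.02: residual intradomain bridge formation).
#' @return a [KineticScheme-class].
#' @examples
#' sch <- buildScheme(rateParameters(), "WT")
#' generator(sch, mg = 1)
#' @export
buildScheme <- function(params, variant = c("WT", "2E2Q", "R447G", "custom"),
                        r447gScale = 0.02) {
  stopifnot(is(params, "RateParameters"))
  validObject(params)
  variant <- match.arg(variant)
  if (variant == "2E2Q") {
    params@kOn <- 0; params@kCat <- 0; params@kFormCC <- 0
  } else if (variant == "R447G") {
    stopifnot(r447gScale >= 0)
    params@kFormOC <- params@kFormOC * r447gScale
  }
  new("KineticScheme", params = params, variant = variant,
      r447gScale = r447gScale)
}

#' Generator matrix of the scheme at a given Mg2+ concentration
#'
#' Returns the 8x8 infinitesimal generator (rate matrix, rows = from-states)
#' over the product states in [schemeStates()] order.  Configuration
#' transitions occur within each gate state: bridge disruption `B_* -> EMG` at
#' `k_cat * mg` and `B_* -> APO` at `k_break0`; bridge formation `APO -> B_CC`
#' at `k_form_CC` and `APO -> B_OC` at `k_form_OC`; Mg exchange `APO -> EMG`
#' at `k_on * mg` and `EMG -> APO` at `k_off`.  Gate transitions:
#' `(CLOSED,B_OC) -> (OPEN,B_OC)` at `k_gate_open`; latched closing
#' `(OPEN,B_CC) -> (CLOSED,B_CC)` at `k_gate_close`; unlatched closing
#' `(OPEN,c) -> (CLOSED,c)` for every configuration at `k_gate_close0`.
#'
#' @param scheme a [KineticScheme-class].
#' @param mg Mg2+ concentration in mM (scalar, >= 0).
#' @return 8x8 numeric matrix with zero row sums.
#' @export
setGeneric("generator", function(scheme, mg) standardGeneric("generator"))

#' @rdname generator
setMethod("generator", "KineticScheme", function(scheme, mg) {
  stopifnot(is.numeric(mg), length(mg) == 1L, is.finite(mg), mg >= 0)
  p <- scheme@params
  st <- schemeStates()
  Q <- matrix(0, 8L, 8L, dimnames = list(st, st))
  put <- function(from, to, rate) {
    i <- .stateIndex(from); j <- .stateIndex(to)
    Q[i, j] <<- Q[i, j] + rate
  }
  for (g in gateStates()) {
    s <- function(cfg) paste(g, cfg, sep = ".")
    put(s("B_CC"), s("EMG"), p@kCat * mg)
    put(s("B_CC"), s("APO"), p@kBreak0)
    put(s("APO"), s("B_CC"), p@kFormCC)
    put(s("APO"), s("B_OC"), p@kFormOC)
    put(s("APO"), s("EMG"), p@kOn * mg)
    put(s("EMG"), s("APO"), p@kOff)
    put(s("B_OC"), s("EMG"), p@kCat * mg)
    put(s("B_OC"), s("APO"), p@kBreak0)
  }
  put("CLOSED.B_OC", "OPEN.B_OC", p@kGateOpen)
  put("OPEN.B_CC", "CLOSED.B_CC", p@kGateClose)
  for (cfg in configStates())
    put(paste("OPEN", cfg, sep = "."), paste("CLOSED", cfg, sep = "."),
        p@kGateClose0)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
})

## states reachable from `start` in the directed transition graph of Q
.reachable <- function(Q, start, tol = 0) {
  n <- nrow(Q)
  adj <- Q > tol
  diag(adj) <- FALSE
  seen <- logical(n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

## mean first-passage time from `start` to the set `target`, by solving the
## linear system on the generator restricted to non-target states.
## Returns Inf when target is unreachable from start.
.mfpt <- function(Q, start, target) {
  reach <- .reachable(Q, start)
  if (any(reach %in% target)) {
    keep <- setdiff(seq_len(nrow(Q)), target)
    Qr <- Q[keep, keep, drop = FALSE]
    tau <- tryCatch(solve(-Qr, rep(1, length(keep))),
                    error = function(e)
                      stop("singular restricted generator while computing ",
                           "first-passage time: ", conditionMessage(e)))
    tau[match(start, keep)]
  } else {
    Inf
  }
}

#' Effective gate opening and closing rates
#'
#' Computes the effective (macroscopic) gate rates at a given Mg2+
#' concentration as inverse mean first-passage times (MFPT) on the 8-state
#' chain: `k_open_eff` is the inverse MFPT from the latched closed state
#' `(CLOSED, B_CC)` to any OPEN state, `k_close_eff` the inverse MFPT from
#' `(OPEN, B_OC)` to any CLOSED state, and
#' `k_cycle = 1 / (1/k_open_eff + 1/k_close_eff)` is the full-cycle rate used
#' as the enzymatic-activity proxy.  When the target gate set is unreachable
#' the corresponding rate is reported as exactly 0.
#'
#' @param scheme a [KineticScheme-class].
#' @param mg Mg2+ concentration(s) in mM; vectorized.
#' @return data.frame with columns `mg_mM`, `k_open_eff_s`, `k_close_eff_s`,
#'   `k_cycle_s`.
#' @examples
#' sch <- buildScheme(rateParameters(), "WT")
#' effectiveRates(sch, mg = c(0.3, 1, 3, 10))
#' @export
effectiveRates <- function(scheme, mg) {
  stopifnot(is(scheme, "KineticScheme"), all(mg >= 0))
  open_set <- .stateIndex(paste("OPEN", configStates(), sep = "."))
  closed_set <- .stateIndex(paste("CLOSED", configStates(), sep = "."))
  res <- vapply(mg, function(m) {
    Q <- generator(scheme, m)
    t_open <- .mfpt(Q, .stateIndex("CLOSED.B_CC"), open_set)
    t_close <- .mfpt(Q, .stateIndex("OPEN.B_OC"), closed_set)
    ko <- if (is.finite(t_open)) 1 / t_open else 0
    kc <- if (is.finite(t_close)) 1 / t_close else 0
    kcyc <- if (ko > 0 && kc > 0) 1 / (1 / ko + 1 / kc) else 0
    c(ko, kc, kcyc)
  }, numeric(3L))
  data.frame(mg_mM = mg, k_open_eff_s = res[1L, ], k_close_eff_s = res[2L, ],
             k_cycle_s = res[3L, ])
}

#' Predicted macro-dwell rates as seen in dwell tables
#'
#' Inverse mean gate macro-dwells as they appear in coarse-grained dwell
#' data.  Open dwells always begin at `(OPEN, B_OC)` -- gate opening is the
#' only entry into the open macro-state -- so the observed closing rate is
#' the plain inverse MFPT, `k_close_eff`.  Closed dwells begin in whichever
#' configuration the gate closed from (latched closing from `B_CC`, unlatched
#' from any configuration), so the mean closed dwell is the mean
#' first-passage time to reopening averaged over the stationary closing-flux
#' entry distribution.  Unlatched closures from `B_OC` reopen quickly, which
#' makes the observed opening rate exceed `k_open_eff` wherever that flicker
#' channel carries weight; this is the phase-type dwell structure the dwell
#' generator produces and the quantity the mechanistic fit matches to data.
#'
#' @param scheme a [KineticScheme-class].
#' @param mg Mg2+ concentration(s) in mM; vectorized.
#' @return data.frame with columns `mg_mM`, `k_open_obs_s` (inverse mean
#'   closed macro-dwell), `k_close_obs_s` (inverse mean open macro-dwell).
#' @seealso [effectiveRates()] for the latched-state (MFPT) effective rates.
#' @export
expectedDwellRates <- function(scheme, mg) {
  stopifnot(is(scheme, "KineticScheme"), all(mg >= 0))
  p <- scheme@params
  open_set <- .stateIndex(paste("OPEN", configStates(), sep = "."))
  closed_set <- .stateIndex(paste("CLOSED", configStates(), sep = "."))
  res <- vapply(mg, function(m) {
    Q <- generator(scheme, m)
    ## direct balance solve when the chain is irreducible (the common case);
    ## fall back to the communicating-class analysis otherwise
    pi <- tryCatch({
      A <- t(Q); A[nrow(Q), ] <- 1
      v <- solve(A, c(rep(0, nrow(Q) - 1L), 1))
      if (any(v < -1e-9)) stop("not irreducible")
      setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(Q))
    }, error = function(e) stationaryDistribution(scheme, m))
    ## MFPT to reopening from every closed state (one solve)
    tau_c <- solve(-Q[closed_set, closed_set, drop = FALSE],
                   rep(1, length(closed_set)))
    ## closing flux into each closed configuration
    flux <- vapply(configStates(), function(cfg) {
      pi[[paste("OPEN", cfg, sep = ".")]] *
        (p@kGateClose0 + (cfg == "B_CC") * p@kGateClose)
    }, numeric(1L))
    if (sum(flux) <= 0) return(c(NA_real_, NA_real_))
    w <- flux / sum(flux)
    mean_closed <- sum(w * tau_c)
    mean_open <- .mfpt(Q, .stateIndex("OPEN.B_OC"), closed_set)
    c(1 / mean_closed, 1 / mean_open)
  }, numeric(2L))
  data.frame(mg_mM = mg, k_open_obs_s = res[1L, ], k_close_obs_s = res[2L, ])
}

#' Stationary distribution of the scheme
#'
#' Long-run occupancy of the 8 product states at a given Mg2+ concentration,
#' computed as the normalized null vector of the transposed generator on the
#' closed communicating class.  States outside that class get occupancy 0.
#' With more than one closed class the long-run occupancy is ambiguous and an
#' error naming the classes is raised.
#'
#' @param scheme a [KineticScheme-class].
#' @param mg Mg2+ concentration in mM.
#' @param start optional state label: restrict to the closed communicating
#'   class reachable from this state.  Without it the chain must have a
#'   unique closed class.
#' @return named numeric vector over [schemeStates()], nonnegative, summing
#'   to 1.
#' @export
stationaryDistribution <- function(scheme, mg, start = NULL) {
  Q <- generator(scheme, mg)
  n <- nrow(Q)
  ## closed communicating classes: states from which every reachable state
  ## reaches back
  reach <- lapply(seq_len(n), function(i) .reachable(Q, i))
  closed <- vapply(seq_len(n), function(i)
    all(vapply(reach[[i]], function(j) i %in% reach[[j]], logical(1L))),
    logical(1L))
  classes <- unique(lapply(which(closed), function(i) sort(reach[[i]])))
  if (!is.null(start)) {
    from <- reach[[.stateIndex(start)]]
    classes <- Filter(function(cl) all(cl %in% from), classes)
  }
  if (length(classes) != 1L)
    stop("chain has ", length(classes), " closed communicating classes",
         if (!is.null(start)) paste0(" reachable from ", start), " (",
         paste(vapply(classes, function(cl)
           paste(rownames(Q)[cl], collapse = "+"), character(1L)),
           collapse = "; "),
         "); long-run occupancy is ambiguous")
  cl <- classes[[1L]]
  pi_full <- setNames(numeric(n), rownames(Q))
  if (length(cl) == 1L) {
    pi_full[cl] <- 1
    return(pi_full)
  }
  Qc <- Q[cl, cl, drop = FALSE]
  diag(Qc) <- 0
  diag(Qc) <- -rowSums(Qc)
  ## solve pi %*% Qc = 0, sum(pi) = 1 by replacing one balance equation
  A <- t(Qc)
  A[length(cl), ] <- 1
  b <- c(rep(0, length(cl) - 1L), 1)
  pi <- solve(A, b)
  pi[abs(pi) < 1e-14] <- 0
  if (any(pi < 0)) stop("numerical failure: negative stationary occupancy")
  pi_full[cl] <- pi / sum(pi)
  pi_full
}

#' Propagate the chemical master equation
#'
#' Evolves a probability vector `p0` under the generator at fixed Mg2+ using
#' the matrix exponential, `p(t) = p0 expm(Q t)`.
#'
#' @param scheme a [KineticScheme-class].
#' @param mg Mg2+ concentration in mM.
#' @param p0 initial probability vector over [schemeStates()] (or a single
#'   state label).
#' @param times numeric vector of times (s).
#' @return matrix `length(times) x 8` of state probabilities.
#' @export
propagateMaster <- function(scheme, mg, p0, times) {
  Q <- generator(scheme, mg)
  if (is.character(p0)) {
    v <- setNames(numeric(8L), schemeStates())
    v[.stateIndex(p0)] <- 1
    p0 <- v
  }
  stopifnot(length(p0) == 8L, abs(sum(p0) - 1) < 1e-8)
  ## eigendecomposition of the transposed generator; fall back to scaling &
  ## squaring through Matrix::expm if defective
  out <- t(vapply(times, function(tt) {
    as.numeric(p0 %*% as.matrix(Matrix::expm(Q * tt)))
  }, numeric(8L)))
  colnames(out) <- schemeStates()
  out
}

#' Calibrate the reference parameter set
#'
#' Produces the package's reference WT parameter set: starting from the base
#' rates in [rateParameters()], a one-dimensional root find on `k_cat` places
#' the interior maximum of the effective opening rate at `target_peak_mg`, and
#' a global rescaling of all rates (which leaves the peak position unchanged)
#' sets the peak opening rate to `target_rate_at_peak`.
#'
#' @param target_peak_mg Mg2+ concentration of the opening-rate optimum (mM);
#'   default 1 mM, the experimentally observed optimum.
#' @param target_rate_at_peak effective opening rate at the optimum (/s);
#'   default 0.5 /s, a typical single-molecule gate rate scale.
#' @param base starting [RateParameters-class]; default [rateParameters()].
#' @param mgBracket interval (mM) searched for the interior optimum.
#' @return a calibrated [RateParameters-class].
#' @examples
#' ref <- calibrateReference()
#' effectiveRates(buildScheme(ref, "WT"), mg = 1)
#' @export
calibrateReference <- function(target_peak_mg = 1.0, target_rate_at_peak = 0.5,
                               base = rateParameters(),
                               mgBracket = c(0.02, 50)) {
  stopifnot(target_peak_mg > 0, target_rate_at_peak > 0)
  peak_of <- function(k_cat) {
    p <- base
    p@kCat <- k_cat
    sch <- buildScheme(p, "WT")
    opt <- stats::optimize(function(lm)
      effectiveRates(sch, exp(lm))$k_open_eff_s,
      interval = log(mgBracket), maximum = TRUE, tol = 1e-8)
    exp(opt$maximum)
  }
  f <- function(log_kcat) log(peak_of(exp(log_kcat))) - log(target_peak_mg)
  lo <- log(1e-3); hi <- log(1e4)
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("no interior opening-rate maximum at the target Mg within the ",
         "k_cat bracket; calibration impossible for these base rates")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)
  p <- base
  p@kCat <- exp(root$root)
  sch <- buildScheme(p, "WT")
  peak_mg <- peak_of(p@kCat)
  rate_at_peak <- effectiveRates(sch, peak_mg)$k_open_eff_s
  s <- target_rate_at_peak / rate_at_peak
  ## uniform rescaling of the generator scales all MFPTs by 1/s
  p@kOn <- p@kOn * s; p@kOff <- p@kOff * s; p@kCat <- p@kCat * s
  p@kBreak0 <- p@kBreak0 * s; p@kFormCC <- p@kFormCC * s
  p@kFormOC <- p@kFormOC * s; p@kGateOpen <- p@kGateOpen * s
  p@kGateClose <- p@kGateClose * s; p@kGateClose0 <- p@kGateClose0 * s
  validObject(p)
  p
}
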