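## Synthetic single-molecule data generation: exact stochastic simulation of
## the gate scheme, noisy extension traces at the instrument's sampling rate,
## dwell-time datasets with experiment-scale event counts, hairpin
## gate-opening assay bookkeeping, and toy coordinate trajectories.

.pathFromSsa <- function(ssa, states, duration, mg, seed) {
  new("StatePath", states = states[ssa$states], entryTime = ssa$entry,
      duration = duration, mg = mg, seed = as.integer(seed))
}

## latched closed start state; for 2E2Q the interdomain bridge cannot form,
## so the physical resting closed state is the apo configuration
.defaultStart <- function(scheme) {
  if (scheme@variant == "2E2Q") "CLOSED.APO" else "CLOSED.B_CC"
}

#' Simulate a gate state path by exact stochastic simulation
#'
#' Gillespie (direct-method) realization of the 8-state salt-bridge-switch
#' chain at fixed Mg2+.  Dwells in each visited state are exponential with
#' that state's total exit rate; a start state with zero exit rate yields a
#' single dwell spanning the whole window.
#'
#' @param scheme a [KineticScheme-class].
#' @param mg Mg2+ concentration (mM).
#' @param duration simulated time window (s), > 0.
#' @param seed integer RNG seed (paths are bit-reproducible given the seed).
#' @param start starting state label; default the latched closed state
#'   `"CLOSED.B_CC"` (`"CLOSED.APO"` for 2E2Q, whose interdomain bridge
#'   cannot form).
#' @return a [StatePath-class].
#' @examples
#' sch <- buildScheme(calibrateReference(), "WT")
#' simulateStatePath(sch, mg = 3, duration = 60, seed = 1)
#' @export
simulateStatePath <- function(scheme, mg, duration, seed, start = NULL) {
  stopifnot(is(scheme, "KineticScheme"), duration > 0)
  if (is.null(start)) start <- .defaultStart(scheme)
  Q <- generator(scheme, mg)
  set.seed(as.integer(seed))
  ssa <- .ssaPathC(Q, .stateIndex(start), duration)
  .pathFromSsa(ssa, schemeStates(), duration, mg, seed)
}

.gateOf <- function(states) sub("\\..*$", "", states)

## coarse-grain a StatePath to gate macro-sojourns
## returns data.frame(state, duration_s, boundary)
.macroDwells <- function(path) {
  gate <- .gateOf(path@states)
  r <- rle(gate)
  k <- length(r$lengths)
  starts <- path@entryTime[cumsum(c(1L, r$lengths[-k]))]
  ends <- c(starts[-1L], path@duration)
  data.frame(state = r$values, duration_s = ends - starts,
             boundary = seq_len(k) %in% c(1L, k))
}

#' Render a noisy extension trace from a state path
#'
#' Converts a [StatePath-class] to a uniformly sampled extension time series:
#' `extension = baseline + amplitude * [gate open] + N(0, noise_sd)`,
#' emulating bead-height tracking of the protein-DNA gate (~6 nm open-closed
#' amplitude, 200 Hz camera).
#'
#' @param path a [StatePath-class].
#' @param amplitude open-minus-closed extension difference (nm); default 6.
#' @param noise_sd Gaussian measurement noise sd (nm); default 2.
#' @param rate sampling rate (Hz); default 200.
#' @param seed integer RNG seed for the noise.
#' @param baseline closed-state extension (nm); default 0.
#' @param force nominal applied force recorded in the metadata (pN).
#' @return an [ExtensionTrace-class] with `floor(duration * rate)` samples.
#' @export
renderExtensionTrace <- function(path, amplitude = 6, noise_sd = 2,
                                 rate = 200, seed = 1L, baseline = 0,
                                 force = 6) {
  stopifnot(is(path, "StatePath"), amplitude > 0, rate > 0, noise_sd >= 0)
  n <- floor(path@duration * rate)
  if (n < 1L) stop("path too short to render at this sampling rate")
  tt <- (seq_len(n) - 1L) / rate
  idx <- findInterval(tt, path@entryTime)
  open <- .gateOf(path@states)[idx] == "OPEN"
  set.seed(as.integer(seed))
  ext <- baseline + amplitude * open +
    if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  new("ExtensionTrace", time = tt, extension = ext,
      metadata = list(mg_mM = path@mg, force_pN = force,
                      amplitude_nm = amplitude, noise_sd_nm = noise_sd,
                      rate_hz = rate, seed = as.integer(seed)))
}

#' Generate a dwell-time dataset across Mg2+ conditions
#'
#' Simulates gate trajectories for each Mg2+ condition, coarse-grains them to
#' gate macro-states (open = any state with the gate open), and collects
#' exactly `n` complete (non-boundary) open and `n` closed dwells per
#' condition.  Macro-dwells are phase-type distributed -- sums over the hidden
#' salt-bridge configurations -- not forced exponential.  Boundary (first and
#' last) dwells of each simulated stretch are flagged, not dropped.
#'
#' @param params a [RateParameters-class].
#' @param variant variant tag passed to [buildScheme()].
#' @param mg numeric vector of Mg2+ concentrations (mM).
#' @param n integer vector (recycled) of complete dwells per state to collect
#'   at each concentration.  The experimentally measured event counts at
#'   0.3/1/3/10 mM were 61/274/313/58.
#' @param seed integer seed.
#' @param r447gScale passed to [buildScheme()].
#' @return data.frame with columns `state`, `duration_s`, `mg_mM`, `trace_id`,
#'   `boundary`.
#' @examples
#' dw <- generateDwellDataset(calibrateReference(), "WT", mg = c(0.3, 3),
#'                            n = c(20, 20), seed = 1)
#' table(dw$mg_mM, dw$state)
#' @export
generateDwellDataset <- function(params, variant = "WT",
                                 mg = c(0.3, 1, 3, 10),
                                 n = c(61L, 274L, 313L, 58L), seed = 1L,
                                 r447gScale = 0.02) {
  stopifnot(length(mg) >= 1L, all(n >= 1L))
  n <- as.integer(rep_len(n, length(mg)))
  scheme <- buildScheme(params, variant, r447gScale = r447gScale)
  set.seed(as.integer(seed))
  out <- vector("list", length(mg))
  for (i in seq_along(mg)) {
    Q <- generator(scheme, mg[i])
    er <- expectedDwellRates(scheme, mg[i])
    if (!is.finite(er$k_open_obs_s) || !is.finite(er$k_close_obs_s) ||
        er$k_open_obs_s == 0 || er$k_close_obs_s == 0)
      stop("gate does not cycle at mg = ", mg[i], " mM for variant ",
           variant, "; no complete dwells can be generated")
    cycle <- 1 / er$k_open_obs_s + 1 / er$k_close_obs_s
    collected <- list()
    trace_id <- 0L
    need <- function(tab) {
      if (is.null(tab)) return(TRUE)
      ok <- tab[!tab$boundary, ]
      sum(ok$state == "OPEN") < n[i] || sum(ok$state == "CLOSED") < n[i]
    }
    acc <- NULL
    while (need(acc)) {
      trace_id <- trace_id + 1L
      dur <- max(10 * cycle, 1.3 * n[i] * cycle)
      ssa <- .ssaPathC(Q, .stateIndex(.defaultStart(scheme)), dur)
      path <- .pathFromSsa(ssa, schemeStates(), dur, mg[i], seed)
      dw <- .macroDwells(path)
      dw$trace_id <- sprintf("%s_mg%g_%03d", variant, mg[i], trace_id)
      acc <- rbind(acc, dw)
      if (trace_id > 1000L)
        stop("failed to collect ", n[i], " dwells at mg = ", mg[i])
    }
    keep_n <- function(st) {
      rows <- acc[!acc$boundary & acc$state == st, , drop = FALSE]
      rows[seq_len(n[i]), , drop = FALSE]
    }
    sel <- rbind(keep_n("OPEN"), keep_n("CLOSED"))
    bnd <- acc[acc$boundary, , drop = FALSE]
    res <- rbind(sel, bnd)
    res$mg_mM <- mg[i]
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("state", "duration_s", "mg_mM", "trace_id", "boundary")]
}

#' Hairpin gate-opening assay bookkeeping
#'
#' Models the DNA-hairpin gate-opening measurement: at high force the hairpin
#' opens, exposing `2 * stem_bp` nucleotides of ssDNA for the enzyme to bind
#' and cleave; gate closing is inhibited at high force, so the extension gain
#' `dEx` equals the gate amplitude if (and only if) the scheme reaches an OPEN
#' state within the high-force window.  `edta = TRUE` models Mg2+ depletion by
#' chelation (mg = 0 and no spontaneous bridge disruption).
#'
#' @param stem_bp hairpin stem length in base pairs (579 for the assay
#'   substrate, exposing 1158 nucleotides).
#' @param variant variant tag.
#' @param mg Mg2+ concentration (mM); forced to 0 when `edta`.
#' @param edta logical; Mg2+ depletion condition.
#' @param high_force_duration length of the high-force window (s).
#' @param seed integer seed.
#' @param params a [RateParameters-class]; default [calibrateReference()].
#' @param amplitude gate-opening extension gain (nm); default 6.
#' @param nm_per_nt ssDNA extension per nucleotide at high force (nm);
#'   only affects the baseline bookkeeping.
#' @return list with elements `Ex0`, `Ex_max`, `dEx` (nm), `exposed_ssDNA`
#'   (nt), `opened` (logical) and `condition`.
#' @examples
#' generateHairpinAssay(579, "WT", mg = 3, high_force_duration = 60, seed = 1)
#' @export
generateHairpinAssay <- function(stem_bp, variant = "WT", mg = 3,
                                 edta = FALSE, high_force_duration = 60,
                                 seed = 1L, params = calibrateReference(),
                                 amplitude = 6, nm_per_nt = 0.45) {
  stopifnot(stem_bp > 0)
  if (high_force_duration <= 0) stop("high_force_duration must be positive")
  if (edta) {
    mg <- 0
    params@kBreak0 <- 0
  }
  ## gate closing inhibited at high force
  params@kGateClose <- 0
  params@kGateClose0 <- 0
  scheme <- buildScheme(params, variant)
  path <- simulateStatePath(scheme, mg, high_force_duration, seed)
  opened <- any(.gateOf(path@states) == "OPEN")
  exposed <- 2L * as.integer(stem_bp)
  Ex0 <- exposed * nm_per_nt
  dEx <- if (opened) amplitude else 0
  list(Ex0 = Ex0, Ex_max = Ex0 + dEx, dEx = dEx, exposed_ssDNA = exposed,
       opened = opened,
       condition = list(variant = variant, mg_mM = mg, edta = edta))
}

## --- synthetic coordinate trajectories ----------------------------------

## distances (A) of the canonical contacts per configuration label:
## contact = 2.8, broken = 8.0
.configDistances <- function(label) {
  switch(label,
         interdomain = c(d304 = 2.8, d408 = 2.8, d447 = 8.0),
         intradomain = c(d304 = 8.0, d408 = 8.0, d447 = 2.8),
         mixed = c(d304 = 2.8, d408 = 2.8, d447 = 2.8),
         none = c(d304 = 8.0, d408 = 8.0, d447 = 8.0),
         stop("unknown configuration label: ", label))
}

.trajAtomTable <- function() {
  data.frame(
    resno = c(457L, 457L, 457L, 454L, 454L, 454L,
              rep(c(304L, 408L, 447L), each = 4L), 328L),
    resname = c(rep("GLU", 6L), rep("ARG", 12L), "TYR"),
    atom = c("OE1", "OE2", "CD", "OE1", "OE2", "CD",
             rep(c("NH1", "NH2", "NE", "CZ"), 3L), "CA"),
    stringsAsFactors = FALSE)
}

## one frame of ideal (jitter-free) coordinates; charged groups are
## collocated pseudo-atom clusters so contact and centroid distances coincide
.frameGeometry <- function(label, dx) {
  d <- .configDistances(label)
  pos <- rbind(
    matrix(rep(c(0, 0, 0), 3L), ncol = 3L, byrow = TRUE),        # E457
    matrix(rep(c(0, 6, 0), 3L), ncol = 3L, byrow = TRUE),        # E454
    matrix(rep(c(0, -d[["d304"]], 0), 4L), ncol = 3L, byrow = TRUE),   # R304
    matrix(rep(c(0, 6 + d[["d408"]], 0), 4L), ncol = 3L, byrow = TRUE),# R408
    matrix(rep(c(0, 0, -d[["d447"]]), 4L), ncol = 3L, byrow = TRUE),   # R447
    c(15 + dx, 0, 0))                                            # Y328 CA
  pos
}

#' Generate a toy coordinate trajectory of the gate region
#'
#' Emits a multi-frame pseudo-atom trajectory realizing a schedule of
#' salt-bridge configurations (side-chain charged atoms of E454/E457 and
#' R304/R408/R447, plus the CA of the catalytic tyrosine Y328), with the
#' scheduled configuration's canonical contacts at 2.8 A and the alternative
#' contacts at 8.0 A, the tyrosine displaced along the force axis (+x)
#' following `opening_profile`, and optional Gaussian coordinate jitter.
#' Each charged group is a collocated pseudo-atom cluster, so minimum O-N
#' contact distances and charged-group centroid distances coincide by
#' construction.
#'
#' @param config_schedule data.frame with columns `label` (one of
#'   `"interdomain"`, `"intradomain"`, `"mixed"`, `"none"`) and `n_frames`
#'   (>= 1), or a list of `(label, n_frames)` pairs.
#' @param jitter_sd Gaussian jitter sd per coordinate (A); default 0.
#' @param opening_profile per-frame target displacement (A) of the Y328 CA
#'   along +x; default all 0; recycled/validated to the total frame count.
#' @param seed integer seed (used when `jitter_sd > 0`).
#' @return a [Trajectory-class].
#' @examples
#' sched <- data.frame(label = c("interdomain", "intradomain"),
#'                     n_frames = c(5, 5))
#' traj <- generateSyntheticTrajectory(sched,
#'   opening_profile = c(rep(0, 5), seq(0, 30, length.out = 5)))
#' gateCoordinates(traj)
#' @export
generateSyntheticTrajectory <- function(config_schedule, jitter_sd = 0,
                                        opening_profile = NULL, seed = 1L) {
  if (is.list(config_schedule) && !is.data.frame(config_schedule))
    config_schedule <- data.frame(
      label = vapply(config_schedule, function(p) as.character(p[[1L]]),
                     character(1L)),
      n_frames = vapply(config_schedule, function(p) as.integer(p[[2L]]),
                        integer(1L)))
  stopifnot(is.data.frame(config_schedule),
            all(c("label", "n_frames") %in% names(config_schedule)),
            all(config_schedule$n_frames >= 1L), jitter_sd >= 0)
  labels <- rep(config_schedule$label, config_schedule$n_frames)
  nf <- length(labels)
  if (is.null(opening_profile)) opening_profile <- numeric(nf)
  stopifnot(length(opening_profile) == nf)
  atoms <- .trajAtomTable()
  coords <- array(NA_real_, dim = c(nf, nrow(atoms), 3L))
  for (f in seq_len(nf))
    coords[f, , ] <- .frameGeometry(labels[f], opening_profile[f])
  if (jitter_sd > 0) {
    set.seed(as.integer(seed))
    coords <- coords + stats::rnorm(length(coords), 0, jitter_sd)
  }
  new("Trajectory", atoms = atoms, coords = coords)
}
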