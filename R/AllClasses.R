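#' @import methods
NULL

## Canonical state-space bookkeeping --------------------------------------

#' Gate and salt-bridge configuration labels
#'
#' The gate model lives on the product space of a gate coordinate
#' (`CLOSED`/`OPEN`) and a salt-bridge configuration of the acidic triad
#' (E454/E457/E458) in domain II:
#' \describe{
#'   \item{`B_CC`}{interdomain ("closed-competent") bridge formed
#'     (E457--R304 / E454--R408); latches the gate closed.}
#'   \item{`APO`}{all bridges broken, no magnesium bound at the triad.}
#'   \item{`EMG`}{bridges broken with Mg2+ bound at the triad (the
#'     \verb{[E+Mg]} state).}
#'   \item{`B_OC`}{intradomain ("open-competent") bridge formed
#'     (E457--R447); licenses gate opening.}
#' }
#'
#' @return `configStates()` and `gateStates()` return the label vectors;
#'   `schemeStates()` returns the 8 product-state names in canonical order
#'   (`"CLOSED.B_CC"`, ..., `"OPEN.B_OC"`).
#' @export
configStates <- function() c("B_CC", "APO", "EMG", "B_OC")

#' @rdname configStates
#' @export
gateStates <- function() c("CLOSED", "OPEN")

#' @rdname configStates
#' @export
schemeStates <- function() {
  as.vector(outer(configStates(), gateStates(),
                  function(cfg, g) paste(g, cfg, sep = ".")))
}

.stateIndex <- function(state) {
  i <- match(state, schemeStates())
  if (anyNA(i)) stop("unknown state label(s): ",
                     paste(state[is.na(i)], collapse = ", "))
  i
}

#' Microscopic rate constants of the salt-bridge-switch scheme
#'
#' Holds the nine microscopic rate constants of the Mg2+-catalyzed
#' salt-bridge-switch model of the type IA topoisomerase protein-DNA gate.
#' Units are per second, except `kOn` and `kCat` which are per mM per second
#' (they multiply the Mg2+ concentration).
#'
#' @slot kOn Mg2+ association to the broken-bridge apo state (/mM/s).
#' @slot kOff Mg2+ dissociation from the acidic triad (/s).
#' @slot kCat Mg2+-catalyzed disruption of a formed bridge (/mM/s).
#' @slot kBreak0 spontaneous, Mg-free bridge disruption (/s).
#' @slot kFormCC formation of the interdomain closed-competent bridge from
#'   the apo state (/s).
#' @slot kFormOC formation of the intradomain open-competent bridge from the
#'   apo state (/s).
#' @slot kGateOpen gate opening while the open-competent bridge is formed (/s).
#' @slot kGateClose latched gate closing while the closed-competent bridge is
#'   formed (/s).
#' @slot kGateClose0 unlatched, configuration-independent gate closing (/s);
#'   must not exceed `kGateClose`.
#' @seealso [rateParameters()], [buildScheme()]
#' @export
setClass("RateParameters",
  representation(kOn = "numeric", kOff = "numeric", kCat = "numeric",
                 kBreak0 = "numeric", kFormCC = "numeric", kFormOC = "numeric",
                 kGateOpen = "numeric", kGateClose = "numeric",
                 kGateClose0 = "numeric"),
  validity = function(object) {
    v <- rateVector(object)
    if (any(!is.finite(v))) return("all rates must be finite")
    if (any(v < 0)) {
      bad <- names(v)[v < 0]
      return(paste0("negative rate(s): ", paste(bad, collapse = ", ")))
    }
    if (object@kGateClose0 > object@kGateClose)
      return("kGateClose0 must not exceed kGateClose")
    TRUE
  })

#' The salt-bridge-switch kinetic scheme
#'
#' An 8-state continuous-time Markov model on
#' \{CLOSED, OPEN\} x \{B_CC, APO, EMG, B_OC\} whose generator depends on the
#' Mg2+ concentration.  Variant tags apply the mutant rate modifiers: `2E2Q`
#' removes the Mg site and the interdomain bridge (`kOn = kCat = kFormCC = 0`),
#' `R447G` scales the intradomain bridge formation rate `kFormOC` by
#' `r447gScale` (default 0.02, leaving the residual dynamics seen for that
#' mutant at saturating Mg).
#'
#' @slot params a [RateParameters-class] object (variant modifiers already
#'   applied).
#' @slot variant one of `"WT"`, `"2E2Q"`, `"R447G"`, `"custom"`.
#' @slot r447gScale numeric multiplier applied to `kFormOC` for `R447G`.
#' @seealso [buildScheme()], [generator()], [effectiveRates()]
#' @export
setClass("KineticScheme",
  representation(params = "RateParameters", variant = "character",
                 r447gScale = "numeric"),
  validity = function(object) {
    if (length(object@variant) != 1L ||
        !object@variant %in% c("WT", "2E2Q", "R447G", "custom"))
      return("variant must be one of WT, 2E2Q, R447G, custom")
    TRUE
  })

#' A simulated state path of the gate model
#'
#' Piecewise-constant realization of the 8-state chain: state labels and the
#' times at which each state was entered, over a fixed total duration.
#'
#' @slot states character vector of visited product-state labels.
#' @slot entryTime numeric vector of entry times (s), starting at 0, strictly
#'   increasing, same length as `states`.
#' @slot duration total simulated duration (s).
#' @slot mg Mg2+ concentration (mM) of the simulation.
#' @slot seed integer seed used.
#' @seealso [simulateStatePath()], [renderExtensionTrace()]
#' @export
setClass("StatePath",
  representation(states = "character", entryTime = "numeric",
                 duration = "numeric", mg = "numeric", seed = "integer"),
  validity = function(object) {
    n <- length(object@states)
    if (length(object@entryTime) != n)
      return("states and entryTime must have equal length")
    if (n == 0L) return("path must contain at least one state")
    if (object@entryTime[1L] != 0) return("first entry time must be 0")
    if (n > 1L) {
      if (any(diff(object@entryTime) <= 0))
        return("entry times must be strictly increasing")
      if (any(object@states[-1L] == object@states[-n]))
        return("consecutive states must differ")
    }
    if (object@duration < object@entryTime[n])
      return("duration must cover the last entry time")
    TRUE
  })

#' A synthetic magnetic-tweezers extension trace
#'
#' Uniformly sampled DNA extension time series rendered from a
#' [StatePath-class]:
#' a two-level signal (closed baseline, open baseline + amplitude) with iid
#' Gaussian noise, emulating bead-height tracking of the ~6 nm gate motion.
#'
#' @slot time sample times (s), uniform at `rate` Hz.
#' @slot extension extension (nm).
#' @slot metadata named list: `mg_mM`, `force_pN`, `amplitude_nm`,
#'   `noise_sd_nm`, `rate_hz`, `seed`.
#' @seealso [renderExtensionTrace()], [idealizeTrace()]
#' @export
setClass("ExtensionTrace",
  representation(time = "numeric", extension = "numeric", metadata = "list"),
  validity = function(object) {
    if (length(object@time) != length(object@extension))
      return("time and extension must have equal length")
    if (any(!is.finite(object@extension)))
      return("extension values must be finite")
    TRUE
  })

#' An idealized (two-state labelled) extension trace
#'
#' Frame-wise open/closed labels plus the fitted emission model from trace
#' idealization.
#'
#' @slot labels character vector, `"OPEN"`/`"CLOSED"`, one per frame.
#' @slot levels named numeric: fitted mean extension (nm) of `CLOSED` and
#'   `OPEN`; `levels["OPEN"] >= levels["CLOSED"]`.
#' @slot noiseSd fitted emission standard deviation(s) (nm).
#' @slot rate sampling rate (Hz) inherited from the trace.
#' @slot method `"hmm"` or `"threshold"`.
#' @seealso [idealizeTrace()], [extractDwells()]
#' @export
setClass("IdealizedPath",
  representation(labels = "character", levels = "numeric", noiseSd = "numeric",
                 rate = "numeric", method = "character"),
  validity = function(object) {
    if (!all(object@labels %in% c("OPEN", "CLOSED")))
      return("labels must be OPEN or CLOSED")
    if (all(c("OPEN", "CLOSED") %in% names(object@levels)) &&
        object@levels[["OPEN"]] < object@levels[["CLOSED"]])
      return("OPEN level must be >= CLOSED level")
    TRUE
  })

#' A multi-frame coordinate trajectory
#'
#' Ordered coordinate frames over a fixed atom set, as read from (or written
#' to) a multi-MODEL PDB file.  The atom table identifies atoms by residue
#' number, residue name and atom name; coordinates are in Angstrom, with the
#' pulling-force axis along +x by convention.
#'
#' @slot atoms data.frame with columns `resno`, `resname`, `atom` (one row per
#'   atom, constant across frames).
#' @slot coords numeric array `frames x atoms x 3` (x, y, z in Angstrom).
#' @seealso [readTrajectory()], [generateSyntheticTrajectory()],
#'   [gateCoordinates()]
#' @export
setClass("Trajectory",
  representation(atoms = "data.frame", coords = "array"),
  validity = function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[3L] != 3L)
      return("coords must be a frames x atoms x 3 array")
    if (d[2L] != nrow(object@atoms))
      return("coords atom dimension must match the atom table")
    if (d[1L] < 1L) return("trajectory must contain at least one frame")
    if (any(!is.finite(object@coords)))
      return("coordinates must be finite")
    TRUE
  })

## show methods -----------------------------------------------------------

setMethod("show", "RateParameters", function(object) {
  v <- rateVector(object)
  cat("RateParameters (/s; kOn, kCat in /mM/s)\n")
  print(signif(v, 4))
})

setMethod("show", "KineticScheme", function(object) {
  cat("KineticScheme:", object@variant,
      "variant; 8 states = {CLOSED,OPEN} x {B_CC,APO,EMG,B_OC}\n")
  cat("  generator(scheme, mg) gives the rate matrix at a given [Mg2+] (mM)\n")
})

setMethod("show", "StatePath", function(object) {
  cat(sprintf("StatePath: %d sojourns over %.4g s (mg = %.3g mM, seed %d)\n",
              length(object@states), object@duration, object@mg, object@seed))
  gate <- sub("\\..*$", "", object@states)
  fr <- tapply(c(diff(object@entryTime),
                 object@duration - object@entryTime[length(object@entryTime)]),
               gate, sum) / object@duration
  cat("  time fraction:", paste(sprintf("%s %.3f", names(fr), fr),
                                collapse = ", "), "\n")
})

setMethod("show", "ExtensionTrace", function(object) {
  md <- object@metadata
  cat(sprintf(
    "ExtensionTrace: %d samples at %g Hz (%.4g s), mg = %.3g mM\n",
    length(object@time), md$rate_hz, length(object@time) / md$rate_hz,
    md$mg_mM))
  cat(sprintf("  amplitude %g nm, noise sd %g nm, seed %d\n",
              md$amplitude_nm, md$noise_sd_nm, md$seed))
})

setMethod("show", "IdealizedPath", function(object) {
  r <- rle(object@labels)
  cat(sprintf("IdealizedPath (%s): %d frames, %d segments\n",
              object@method, length(object@labels), length(r$lengths)))
  if (all(c("CLOSED", "OPEN") %in% names(object@levels)))
    cat(sprintf("  levels: CLOSED %.2f nm, OPEN %.2f nm (sd %.2f nm)\n",
                object@levels[["CLOSED"]], object@levels[["OPEN"]],
                mean(object@noiseSd)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames, %d atoms (%d residues)\n",
              nFrames(object), nrow(object@atoms),
              length(unique(object@atoms$resno))))
})

## accessors --------------------------------------------------------------

#' Accessors for gatekin S4 objects
#'
#' Small accessor helpers: `rateVector()` returns the nine rate constants of a
#' [RateParameters-class] (or of a scheme's parameters) as a named numeric
#' vector (names `k_on`, `k_off`, `k_cat`, `k_break0`, `k_form_CC`,
#' `k_form_OC`, `k_gate_open`, `k_gate_close`, `k_gate_close0`); `variant()`
#' returns a scheme's variant tag; `nFrames()` the number of frames of a
#' [Trajectory-class]; `frameCoords()` one frame's coordinates as a data.frame.
#'
#' @param object a gatekin S4 object.
#' @param traj a [Trajectory-class].
#' @param frame 1-based frame index.
#' @export
rateVector <- function(object) {
  if (is(object, "KineticScheme")) object <- object@params
  stopifnot(is(object, "RateParameters"))
  c(k_on = object@kOn, k_off = object@kOff, k_cat = object@kCat,
    k_break0 = object@kBreak0, k_form_CC = object@kFormCC,
    k_form_OC = object@kFormOC, k_gate_open = object@kGateOpen,
    k_gate_close = object@kGateClose, k_gate_close0 = object@kGateClose0)
}

#' @rdname rateVector
#' @export
variant <- function(object) object@variant

#' @rdname rateVector
#' @export
nFrames <- function(traj) dim(traj@coords)[1L]

#' @rdname rateVector
#' @export
frameCoords <- function(traj, frame = 1L) {
  stopifnot(is(traj, "Trajectory"), frame >= 1L, frame <= nFrames(traj))
  cbind(traj@atoms,
        data.frame(x = traj@coords[frame, , 1L],
                   y = traj@coords[frame, , 2L],
                   z = traj@coords[frame, , 3L]))
}

#' Construct a RateParameters object
#'
#' @param k_on,k_off,k_cat,k_break0,k_form_CC,k_form_OC,k_gate_open,k_gate_close,k_gate_close0
#'   the nine microscopic rates; see [RateParameters-class] for meanings and
#'   units.  Defaults are the uncalibrated base set; the reference set used
#'   throughout is produced by [calibrateReference()].
#' @return a validated [RateParameters-class] object.
#' @examples
#' p <- rateParameters()
#' rateVector(p)
#' @export
rateParameters <- function(k_on = 10, k_off = 10, k_cat = 5, k_break0 = 0.01,
                           k_form_CC = 5, k_form_OC = 5, k_gate_open = 20,
                           k_gate_close = 20, k_gate_close0 = 2) {
  new("RateParameters", kOn = k_on, kOff = k_off, kCat = k_cat,
      kBreak0 = k_break0, kFormCC = k_form_CC, kFormOC = k_form_OC,
      kGateOpen = k_gate_open, kGateClose = k_gate_close,
      kGateClose0 = k_gate_close0)
}
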