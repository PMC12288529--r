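## Trace idealization: convert noisy extension traces into two-state
## (open/closed) label sequences, then extract dwell times.  The primary
## decoder is a two-state Gaussian hidden-Markov model fit by
## expectation-maximization and decoded by the most probable (Viterbi) path;
## a median-filter + half-amplitude-threshold method is the fallback.

## merge runs shorter than min_frames into their neighbours, shortest first
.mergeShortRuns <- function(labels, min_frames) {
  if (min_frames <= 1L) return(labels)
  repeat {
    r <- rle(labels)
    k <- length(r$lengths)
    if (k <= 1L) return(labels)
    short <- which(r$lengths < min_frames)
    if (!length(short)) return(labels)
    i <- short[which.min(r$lengths[short])]
    ## flipping a two-state run merges it with both neighbours
    other <- setdiff(unique(labels), r$values[i])[1L]
    from <- sum(r$lengths[seq_len(i - 1L)]) + 1L
    labels[from:(from + r$lengths[i] - 1L)] <- other
  }
}

#' Idealize an extension trace into open/closed states
#'
#' Two-state idealization of a noisy extension trace.  Method `"hmm"` fits a
#' two-state Gaussian hidden-Markov model by expectation-maximization
#' (Baum-Welch, scaled forward-backward) and decodes the most probable state
#' path (Viterbi); method `"threshold"` median-filters the trace (window 5)
#' and splits at the midpoint of the two fitted levels.  In both methods,
#' segments shorter than `min_dwell_frames` are merged into their neighbours
#' (shortest first), imposing a detection dead time of
#' `min_dwell_frames / rate` seconds.
#'
#' @param trace an [ExtensionTrace-class] with at least
#'   `10 * min_dwell_frames` samples.
#' @param method `"hmm"` (default) or `"threshold"`.
#' @param min_dwell_frames minimum retained dwell length in frames; default 3
#'   (15 ms at 200 Hz).
#' @param maxit,tol EM iteration cap and relative log-likelihood tolerance.
#' @return an [IdealizedPath-class].  A zero-variance trace yields a
#'   single-state path with a warning; a trace whose two-level labelling is
#'   not supported against a single Gaussian level (by BIC) collapses to a
#'   single state.
#' @examples
#' sch <- buildScheme(calibrateReference(), "WT")
#' path <- simulateStatePath(sch, mg = 3, duration = 30, seed = 1)
#' tr <- renderExtensionTrace(path, seed = 1)
#' idealizeTrace(tr)
#' @export
idealizeTrace <- function(trace, method = c("hmm", "threshold"),
                          min_dwell_frames = 3L, maxit = 200L, tol = 1e-8) {
  stopifnot(is(trace, "ExtensionTrace"))
  method <- match.arg(method)
  x <- trace@extension
  if (any(!is.finite(x))) stop("trace contains non-finite samples")
  n <- length(x)
  if (n < 10L * min_dwell_frames)
    stop("trace too short: need at least ", 10L * min_dwell_frames,
         " samples")
  rate <- trace@metadata$rate_hz
  if (stats::sd(x) == 0) {
    warning("zero-variance trace: returning a single-state path")
    return(new("IdealizedPath", labels = rep("CLOSED", n),
               levels = c(CLOSED = x[1L], OPEN = x[1L]), noiseSd = 0,
               rate = rate, method = method))
  }
  mu0 <- unname(stats::quantile(x, c(0.15, 0.85)))
  if (diff(mu0) < 1e-12) mu0 <- mu0 + c(-1, 1) * stats::sd(x)
  sd0 <- rep(stats::sd(x) / 2, 2L)
  A0 <- matrix(c(0.99, 0.01, 0.01, 0.99), 2L, 2L)
  fit <- .hmm2EmC(x, mu0, sd0, A0, c(0.5, 0.5), as.integer(maxit), tol)
  ## one state or two?  BIC on the marginal likelihood: single Gaussian
  ## level (2 parameters) vs the two-state Gaussian HMM (7 parameters).
  ## A constant-plus-noise trace has no resolvable two-state structure.
  ll1 <- sum(stats::dnorm(x, mean(x), stats::sd(x), log = TRUE))
  if (-2 * ll1 + 2 * log(n) <= -2 * fit$logLik + 7 * log(n)) {
    lv <- mean(x)
    return(new("IdealizedPath", labels = rep("CLOSED", n),
               levels = c(CLOSED = lv, OPEN = lv),
               noiseSd = stats::sd(x), rate = rate, method = method))
  }
  if (method == "hmm") {
    lab12 <- .hmm2ViterbiC(x, fit$mu, fit$sd, fit$A, fit$pi)
    lo <- which.min(fit$mu)
    labels <- ifelse(lab12 == lo, "CLOSED", "OPEN")
    levels <- c(CLOSED = fit$mu[lo], OPEN = fit$mu[3L - lo])
    noise <- fit$sd[c(lo, 3L - lo)]
  } else {
    xf <- stats::runmed(x, 5L)
    km <- stats::kmeans(xf, centers = matrix(
      unname(stats::quantile(xf, c(0.1, 0.9))), ncol = 1L))
    lo <- which.min(km$centers)
    mid <- mean(km$centers)
    labels <- ifelse(xf > mid, "OPEN", "CLOSED")
    levels <- c(CLOSED = km$centers[lo], OPEN = km$centers[3L - lo])
    noise <- stats::sd(x - km$centers[km$cluster])
  }
  labels <- .mergeShortRuns(labels, as.integer(min_dwell_frames))
  ## refit levels on the final labelling
  for (st in c("CLOSED", "OPEN"))
    if (any(labels == st)) levels[[st]] <- mean(x[labels == st])
  if (levels[["OPEN"]] < levels[["CLOSED"]])
    levels <- c(CLOSED = min(levels), OPEN = max(levels))
  new("IdealizedPath", labels = labels, levels = levels,
      noiseSd = unname(noise), rate = rate, method = method)
}

#' Extract dwell times from an idealized path
#'
#' One record per maximal constant-label run.  The first and last runs of a
#' trace are right/left-censored (the transition into or out of them was not
#' observed); they are flagged `boundary` and excluded by default.
#'
#' @param path an [IdealizedPath-class].
#' @param drop_boundary drop the censored first/last dwells (default TRUE).
#' @param mg,trace_id condition metadata copied into the table.
#' @return data.frame with columns `state`, `duration_s`, `mg_mM`,
#'   `trace_id`, `boundary`.
#' @export
extractDwells <- function(path, drop_boundary = TRUE, mg = NA_real_,
                          trace_id = NA_character_) {
  stopifnot(is(path, "IdealizedPath"))
  r <- rle(path@labels)
  k <- length(r$lengths)
  tab <- data.frame(state = r$values,
                    duration_s = r$lengths / path@rate,
                    mg_mM = mg, trace_id = trace_id,
                    boundary = seq_len(k) %in% c(1L, k))
  if (drop_boundary) tab <- tab[!tab$boundary, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
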