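## Trajectory operators: salt-bridge detection (distance cutoff between
## acidic side-chain oxygens and basic side-chain nitrogens), charged-group
## centroid distances, gate-opening coordinates of the catalytic tyrosine
## (dx along the pulling force, dy orthogonal), per-frame configuration
## classification, and the configuration/opening correlation summary.

.ACIDIC_O <- c("OE1", "OE2", "OD1", "OD2")
.BASIC_N <- c("NZ", "NH1", "NH2", "NE")
## charged-group atom selections for centroid distances
.CHARGED_GROUP <- list(GLU = c("OE1", "OE2", "CD"),
                       ASP = c("OD1", "OD2", "CG"),
                       ARG = c("NH1", "NH2", "NE", "CZ"),
                       LYS = "NZ")
.ATOM_MASS <- c(C = 12.011, N = 14.007, O = 15.999)

#' Read a multi-MODEL PDB coordinate trajectory
#'
#' Parses a standard multi-MODEL PDB file into a [Trajectory-class], one
#' frame per MODEL, with atoms matched across frames by (residue number,
#' atom name).  Files whose models do not share an identical atom set are
#' rejected with an error naming the offending atoms.
#'
#' @param path path to a PDB file with ATOM records (single- or multi-MODEL).
#' @return a [Trajectory-class].
#' @seealso [writeTrajectoryPDB()], [generateSyntheticTrajectory()]
#' @export
readTrajectory <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  atom_lines <- grepl("^ATOM  |^HETATM", lines)
  model_starts <- grep("^MODEL", lines)
  if (!any(atom_lines)) stop("no ATOM records in ", path)
  if (length(model_starts) <= 1L) {
    frame_id <- rep(1L, sum(atom_lines))
  } else {
    frame_id <- findInterval(which(atom_lines), model_starts)
    if (any(frame_id == 0L))
      stop("ATOM records before the first MODEL in ", path)
  }
  ## consistency check on (resno, atom name) across frames
  al <- lines[atom_lines]
  key <- paste(trimws(substr(al, 23L, 26L)), trimws(substr(al, 13L, 16L)))
  keys <- split(key, frame_id)
  ref_key <- keys[[1L]]
  for (f in seq_along(keys)) {
    if (!identical(keys[[f]], ref_key)) {
      missing <- setdiff(ref_key, keys[[f]])
      extra <- setdiff(keys[[f]], ref_key)
      stop("inconsistent atom set in frame ", f, ": ",
           if (length(missing)) paste0("missing [",
             paste(missing, collapse = ", "), "] "),
           if (length(extra)) paste0("unexpected [",
             paste(extra, collapse = ", "), "]"))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  natom <- nrow(pdb$atom)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, natom, 3L))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  atoms <- data.frame(resno = pdb$atom$resno, resname = pdb$atom$resid,
                      atom = pdb$atom$elety, stringsAsFactors = FALSE)
  new("Trajectory", atoms = atoms, coords = coords)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' Standard ATOM records, one MODEL/ENDMDL block per frame, coordinates to
#' 0.001 Angstrom.  Residue numbering is whatever the trajectory carries
#' (E454/E457/R304/R408/R447/Y328 for the synthetic gate-region
#' trajectories, per the ectopo3 numbering).
#'
#' @param traj a [Trajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  atoms <- traj@atoms
  elem <- substr(atoms$atom, 1L, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(atoms)), atoms$atom, atoms$resname, atoms$resno,
      traj@coords[f, , 1L], traj@coords[f, , 2L], traj@coords[f, , 3L],
      elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Detect salt bridges in a coordinate frame
#'
#' A salt bridge is scored present when the minimum distance between any
#' acidic side-chain oxygen (OE1/OE2/OD1/OD2 of Glu/Asp) and any basic
#' side-chain nitrogen (NZ/NH1/NH2/NE of Lys/Arg) of a residue pair is at or
#' below `cutoff`.
#'
#' @param frame a frame data.frame (`resno`, `resname`, `atom`, `x`, `y`,
#'   `z`), e.g. from [frameCoords()].
#' @param pairs optional restriction: data.frame (or list of length-2
#'   vectors) of `(acidic resno, basic resno)` pairs.  Default: all
#'   acidic-basic residue pairs present in the frame.
#' @param cutoff contact distance cutoff in Angstrom; default 3.2 (the
#'   conventional side-chain O-N salt-bridge criterion).
#' @param frame_index frame index recorded in the output.
#' @return data.frame with columns `acidic`, `basic`, `distance_A`, `frame`,
#'   `present`.
#' @export
detectSaltBridges <- function(frame, pairs = NULL, cutoff = 3.2,
                              frame_index = 1L) {
  stopifnot(is.data.frame(frame),
            all(c("resno", "atom", "x", "y", "z") %in% names(frame)))
  ox <- frame[frame$atom %in% .ACIDIC_O, , drop = FALSE]
  nz <- frame[frame$atom %in% .BASIC_N, , drop = FALSE]
  if (is.null(pairs)) {
    pairs <- expand.grid(acidic = unique(ox$resno), basic = unique(nz$resno))
  } else {
    if (is.list(pairs) && !is.data.frame(pairs))
      pairs <- data.frame(acidic = vapply(pairs, `[`, numeric(1L), 1L),
                          basic = vapply(pairs, `[`, numeric(1L), 2L))
  }
  if (!nrow(pairs)) return(data.frame(acidic = integer(), basic = integer(),
                                      distance_A = numeric(),
                                      frame = integer(), present = logical()))
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- ox[ox$resno == pairs$acidic[i], c("x", "y", "z"), drop = FALSE]
    b <- nz[nz$resno == pairs$basic[i], c("x", "y", "z"), drop = FALSE]
    if (!nrow(a))
      stop("no acidic side-chain oxygens for residue ", pairs$acidic[i])
    if (!nrow(b))
      stop("no basic side-chain nitrogens for residue ", pairs$basic[i])
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") -
      2 * as.matrix(a) %*% t(as.matrix(b))
    data.frame(acidic = pairs$acidic[i], basic = pairs$basic[i],
               distance_A = sqrt(max(min(d2), 0)))
  }))
  res$frame <- as.integer(frame_index)
  res$present <- res$distance_A <= cutoff
  res
}

#' Charged-group centroid distance between two residues
#'
#' Euclidean distance between the centroids of the charged-group atoms of
#' two residues (Glu: OE1/OE2/CD; Asp: OD1/OD2/CG; Arg: NH1/NH2/NE/CZ; Lys:
#' NZ).  Centroids are unweighted by default; `mass_weighted = TRUE` uses
#' element masses.
#'
#' @param frame a frame data.frame (see [detectSaltBridges()]).
#' @param resA,resB residue numbers.
#' @param selection `"charged"` (default, the group atoms above) or a
#'   character vector of atom names applied to both residues.
#' @param mass_weighted weight atoms by element mass; default FALSE.
#' @return distance in Angstrom.
#' @export
comDistance <- function(frame, resA, resB, selection = "charged",
                        mass_weighted = FALSE) {
  centroid <- function(res) {
    sub <- frame[frame$resno == res, , drop = FALSE]
    if (!nrow(sub)) stop("residue ", res, " absent from frame")
    sel <- if (identical(selection, "charged")) {
      grp <- .CHARGED_GROUP[[sub$resname[1L]]]
      if (is.null(grp)) stop("no charged-group selection for residue type ",
                             sub$resname[1L])
      grp
    } else selection
    sub <- sub[sub$atom %in% sel, , drop = FALSE]
    if (!nrow(sub)) stop("empty atom selection for residue ", res)
    wgt <- if (mass_weighted) {
      m <- .ATOM_MASS[substr(sub$atom, 1L, 1L)]
      if (anyNA(m)) stop("unknown element for mass weighting")
      m
    } else rep(1, nrow(sub))
    colSums(sub[, c("x", "y", "z")] * wgt) / sum(wgt)
  }
  sqrt(sum((centroid(resA) - centroid(resB))^2))
}

#' Gate-opening coordinates of the catalytic tyrosine
#'
#' Per-frame displacement of the catalytic tyrosine CA relative to a
#' reference frame: `dx` along the applied-force axis (+x) and `dy`
#' orthogonal to it.
#'
#' @param traj a [Trajectory-class].
#' @param residue tyrosine residue number; default 328 (ectopo3's Y328; use
#'   319 for ectopo1).
#' @param reference_frame 1-based index of the reference frame; default 1.
#' @return data.frame `frame`, `dx_A`, `dy_A`.
#' @export
gateCoordinates <- function(traj, residue = 328L, reference_frame = 1L) {
  stopifnot(is(traj, "Trajectory"),
            reference_frame >= 1L, reference_frame <= nFrames(traj))
  i <- which(traj@atoms$resno == residue & traj@atoms$atom == "CA")
  if (length(i) != 1L)
    stop("CA of residue ", residue, " not found (or not unique) in trajectory")
  x <- traj@coords[, i, 1L]
  y <- traj@coords[, i, 2L]
  data.frame(frame = seq_len(nFrames(traj)),
             dx_A = x - x[reference_frame],
             dy_A = y - y[reference_frame])
}

#' Classify the salt-bridge configuration of a frame
#'
#' Classification from the canonical contacts: `interdomain` when E457-R304
#' is present and E457-R447 absent (closed-competent latch), `intradomain`
#' for the reverse (open-competent), `mixed` when both are present and
#' `none` when neither is.
#'
#' @param events salt-bridge event table (from [detectSaltBridges()])
#'   containing the E457-R304 and E457-R447 pairs, or a named logical vector
#'   with elements `E457_R304` and `E457_R447`.
#' @param acidic,inter_basic,intra_basic residue numbers of the canonical
#'   contacts; defaults E457, R304, R447.
#' @return one of `"interdomain"`, `"intradomain"`, `"mixed"`, `"none"`.
#' @export
classifyConfiguration <- function(events, acidic = 457L, inter_basic = 304L,
                                  intra_basic = 447L) {
  if (is.logical(events)) {
    need <- c("E457_R304", "E457_R447")
    if (!all(need %in% names(events)))
      stop("logical input must name elements E457_R304 and E457_R447")
    inter <- events[["E457_R304"]]; intra <- events[["E457_R447"]]
  } else {
    stopifnot(is.data.frame(events),
              all(c("acidic", "basic", "present") %in% names(events)))
    pick <- function(b) {
      row <- events$acidic == acidic & events$basic == b
      if (!any(row))
        stop("canonical pair E", acidic, "-R", b, " missing from events")
      any(events$present[row])
    }
    inter <- pick(inter_basic); intra <- pick(intra_basic)
  }
  if (inter && intra) "mixed"
  else if (inter) "interdomain"
  else if (intra) "intradomain"
  else "none"
}

#' Correlate salt-bridge configuration with gate opening
#'
#' Labels every frame by its salt-bridge configuration, computes the
#' catalytic-tyrosine gate coordinates, and partitions the frame-to-frame
#' increase of the opening coordinate `dx` by the configuration of the
#' earlier frame.  When the total `dx` increase is positive, the per-label
#' opening fractions sum to 1.
#'
#' @param traj a [Trajectory-class].
#' @param residue catalytic tyrosine residue number; default 328.
#' @param cutoff salt-bridge cutoff (A); default 3.2.
#' @return list: `frames` (per-frame data.frame `frame`, `dx_A`, `dy_A`,
#'   `d_E457_R304_A`, `d_E457_R447_A`, `label`), `frame_fraction` (time
#'   fraction per label), `opening_fraction` (fraction of summed positive
#'   `dx` increments per label) and `total_dx_increase_A`.
#' @export
correlateConfigOpening <- function(traj, residue = 328L, cutoff = 3.2) {
  stopifnot(is(traj, "Trajectory"), nFrames(traj) >= 2L)
  gc <- gateCoordinates(traj, residue = residue)
  canon <- data.frame(acidic = c(457L, 457L), basic = c(304L, 447L))
  per <- lapply(seq_len(nFrames(traj)), function(f) {
    ev <- detectSaltBridges(frameCoords(traj, f), pairs = canon,
                            cutoff = cutoff, frame_index = f)
    list(label = classifyConfiguration(ev),
         d304 = ev$distance_A[ev$basic == 304L],
         d447 = ev$distance_A[ev$basic == 447L])
  })
  frames <- data.frame(
    frame = gc$frame, dx_A = gc$dx_A, dy_A = gc$dy_A,
    d_E457_R304_A = vapply(per, `[[`, numeric(1L), "d304"),
    d_E457_R447_A = vapply(per, `[[`, numeric(1L), "d447"),
    label = vapply(per, `[[`, character(1L), "label"),
    stringsAsFactors = FALSE)
  frame_fraction <- table(frames$label) / nrow(frames)
  inc <- pmax(diff(frames$dx_A), 0)
  lab <- frames$label[-nrow(frames)]
  total <- sum(inc)
  opening_fraction <- if (total > 0) {
    tapply(inc, lab, sum) / total
  } else {
    setNames(rep(NA_real_, length(unique(lab))), unique(lab))
  }
  list(frames = frames,
       frame_fraction = as.numeric(frame_fraction) |>
         setNames(names(frame_fraction)),
       opening_fraction = as.numeric(opening_fraction) |>
         setNames(names(opening_fraction)),
       total_dx_increase_A = total)
}
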