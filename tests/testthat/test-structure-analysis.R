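sim1Schedule <- function() {
  ## opening ramp confined to the intradomain segment, as in a two-state
  ## opening transition
  sched <- data.frame(label = c("interdomain", "intradomain"),
                      n_frames = c(20, 20))
  profile <- c(rep(0, 20), seq(0, 30, length.out = 20))
  generateSyntheticTrajectory(sched, opening_profile = profile)
}

test_that("multi-MODEL PDB round trip preserves coordinates and atom
          identity", {
  tj <- generateSyntheticTrajectory(
    data.frame(label = c("interdomain", "intradomain"), n_frames = c(5, 5)),
    jitter_sd = 0.3, seed = 4)
  f <- tempfile(fileext = ".pdb")
  writeTrajectoryPDB(tj, f)
  back <- readTrajectory(f)
  expect_equal(nFrames(back), 10L)
  expect_equal(back@atoms$resno, tj@atoms$resno)
  expect_equal(back@atoms$atom, tj@atoms$atom)
  expect_lt(max(abs(back@coords - tj@coords)), 1e-3)
})

test_that("inconsistent atom sets across models are rejected with the
          offender named", {
  tj <- generateSyntheticTrajectory(
    data.frame(label = "interdomain", n_frames = 3))
  f <- tempfile(fileext = ".pdb")
  writeTrajectoryPDB(tj, f)
  lines <- readLines(f)
  drop <- which(grepl("CA", lines) & cumsum(grepl("^MODEL", lines)) == 2L)
  writeLines(lines[-drop], f)
  expect_error(readTrajectory(f), "frame 2.*328 CA")
  expect_error(readTrajectory(tempfile()), "exists")
})

test_that("salt-bridge detection takes the minimum over side-chain O-N
          pairs and respects the cutoff", {
  frame <- data.frame(
    resno = c(457L, 457L, 304L, 304L),
    resname = c("GLU", "GLU", "ARG", "ARG"),
    atom = c("OE1", "OE2", "NH1", "NH2"),
    x = c(0, 0, 3.0, 5.0), y = 0, z = c(0, 1, 0, 0))
  ev <- detectSaltBridges(frame)
  expect_equal(ev$distance_A, 3.0)
  expect_true(ev$present)
  far <- frame; far$x[3] <- 3.5
  expect_false(detectSaltBridges(far)$present)
  ## non-O/N atoms are never contact candidates
  withCD <- rbind(frame, data.frame(resno = 457L, resname = "GLU",
                                    atom = "CD", x = 2.9, y = 0, z = 0))
  expect_equal(detectSaltBridges(withCD)$distance_A, 3.0)
  expect_error(detectSaltBridges(frame, pairs = list(c(457, 447))),
               "basic side-chain nitrogens")
})

test_that("the set of detected bridges is non-decreasing in the cutoff", {
  tj <- generateSyntheticTrajectory(
    data.frame(label = "mixed", n_frames = 1), jitter_sd = 0.5, seed = 9)
  fr <- frameCoords(tj, 1)
  prev <- 0L
  for (cut in c(2, 3.2, 5, 9, 20)) {
    now <- sum(detectSaltBridges(fr, cutoff = cut)$present)
    expect_gte(now, prev)
    prev <- now
  }
})

test_that("per-frame operators are invariant to atom-row permutation", {
  tj <- generateSyntheticTrajectory(
    data.frame(label = "interdomain", n_frames = 1), jitter_sd = 0.2,
    seed = 2)
  fr <- frameCoords(tj, 1)
  set.seed(1)
  shuffled <- fr[sample(nrow(fr)), ]
  a <- detectSaltBridges(fr, pairs = list(c(457, 304)))
  b <- detectSaltBridges(shuffled, pairs = list(c(457, 304)))
  expect_equal(a$distance_A, b$distance_A)
  expect_equal(comDistance(fr, 457, 304), comDistance(shuffled, 457, 304))
})

test_that("centroid distances: single atoms, symmetric groups, canonical
          fixture and mass weighting", {
  two <- data.frame(resno = c(1L, 2L), resname = c("LYS", "LYS"),
                    atom = c("NZ", "NZ"), x = c(0, 5), y = 0, z = 0)
  expect_equal(comDistance(two, 1, 2), 5)

  sym <- data.frame(resno = rep(c(1L, 2L), each = 2),
                    resname = "LYS", atom = "NZ",
                    x = c(-1, 1, 9, 11), y = c(2, -2, 3, -3), z = 0)
  expect_equal(comDistance(sym, 1, 2, selection = "NZ"), 10)

  fr <- frameCoords(generateSyntheticTrajectory(
    data.frame(label = "interdomain", n_frames = 1)), 1)
  expect_equal(comDistance(fr, 457, 304), 2.8)
  expect_equal(comDistance(fr, 457, 447), 8.0)
  ## collocated pseudo-atoms: mass weighting changes nothing here
  expect_equal(comDistance(fr, 457, 304, mass_weighted = TRUE), 2.8)
  expect_error(comDistance(fr, 457, 999), "absent")
  expect_error(comDistance(fr, 457, 304, selection = "XX"), "empty")
})

test_that("gate coordinates measure tyrosine displacement relative to the
          reference frame", {
  ramp <- generateSyntheticTrajectory(
    data.frame(label = "intradomain", n_frames = 6),
    opening_profile = c(0, 2, 4, 8, 16, 30))
  gc <- gateCoordinates(ramp)
  expect_equal(gc$dx_A[1], 0)
  expect_equal(gc$dy_A[1], 0)
  expect_equal(gc$dx_A[6], 30)
  gc4 <- gateCoordinates(ramp, reference_frame = 4)
  expect_equal(gc4$dx_A, gc$dx_A - 8)
  ## pure y translation
  tj <- generateSyntheticTrajectory(
    data.frame(label = "none", n_frames = 2))
  tj@coords[2, , 2] <- tj@coords[2, , 2] + 4
  gc2 <- gateCoordinates(tj)
  expect_equal(gc2$dx_A[2], 0)
  expect_equal(gc2$dy_A[2], 4)
  expect_error(gateCoordinates(ramp, residue = 999), "not found")
})

test_that("configuration classifier matches its four-row truth table
          exactly", {
  tab <- expand.grid(inter = c(TRUE, FALSE), intra = c(TRUE, FALSE))
  want <- c("mixed", "intradomain", "interdomain", "none")
  for (i in seq_len(nrow(tab))) {
    got <- classifyConfiguration(c(E457_R304 = tab$inter[i],
                                   E457_R447 = tab$intra[i]))
    expect_identical(got, want[i])
  }
  ev <- detectSaltBridges(frameCoords(generateSyntheticTrajectory(
    data.frame(label = "interdomain", n_frames = 1)), 1),
    pairs = list(c(457, 304), c(457, 447)))
  expect_identical(classifyConfiguration(ev), "interdomain")
  expect_error(classifyConfiguration(ev[ev$basic == 304, ]), "missing")
})

test_that("opening displacement is attributed to the configuration under
          which it accrues", {
  cc <- correlateConfigOpening(sim1Schedule())
  expect_gte(cc$opening_fraction[["intradomain"]], 0.95)
  expect_equal(sum(cc$opening_fraction), 1)
  expect_equal(unname(cc$frame_fraction[c("interdomain", "intradomain")]),
               c(0.5, 0.5))

  ## interdomain throughout, no ramp: nothing to attribute
  sim2 <- generateSyntheticTrajectory(
    data.frame(label = "interdomain", n_frames = 30))
  cc2 <- correlateConfigOpening(sim2)
  expect_equal(cc2$total_dx_increase_A, 0)

  only <- correlateConfigOpening(generateSyntheticTrajectory(
    data.frame(label = "intradomain", n_frames = 10),
    opening_profile = seq(0, 10, length.out = 10)))
  expect_equal(unname(only$opening_fraction[["intradomain"]]), 1)
})
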