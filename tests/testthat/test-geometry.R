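test_that("distance is Euclidean, symmetric, and matches a brute-force oracle", {
  expect_equal(atomDistance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(atomDistance(c(1, 0, 0), c(0, 0, 0)), 1)
  expect_equal(atomDistance(c(1, 2, 2), c(0, 0, 0)), 3)

  set.seed(101)
  for (i in 1:1000) {
    a <- runif(3, -50, 50); b <- runif(3, -50, 50)
    oracle <- sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2)
    expect_equal(atomDistance(a, b), oracle, tolerance = 1e-12)
    expect_identical(atomDistance(a, b), atomDistance(b, a))
  }
})

test_that("hydrogen-bond verdicts respect the cutoffs and the gray zone", {
  expect_equal(callHBond(2.9)$verdict, "bonded")
  expect_equal(callHBond(4.3)$verdict, "not_bonded")  # > 4 A: not bonded
  expect_equal(callHBond(3.7)$verdict, "ambiguous")
  expect_equal(callHBond(3.5)$verdict, "bonded")      # boundary inclusive
  expect_equal(callHBond(4.0)$verdict, "not_bonded")
  expect_equal(callHBond(c(0, 0, 0), c(2.9, 0, 0))$distance, 2.9)
  expect_error(callHBond(3.0, bondedMax = 4.5, brokenMin = 4.0))
})

test_that("conformational classification covers N3, N1, extended and ambiguous", {
  n3 <- classifyConformation(kturnTemplate("N3"))
  expect_equal(n3$cls, "N3")
  expect_equal(n3$d_O2p_N3, 2.9)
  expect_equal(n3$d_O2p_N1, 5.1)
  expect_equal(n3$d_N6_N3, 2.9)
  expect_equal(n3$d_L1_A1n, 2.8)
  expect_equal(n3$pair_3b3n, "AG")

  n1 <- classifyConformation(kturnTemplate("N1"))
  expect_equal(n1$cls, "N1")
  expect_equal(n1$d_O2p_N1, 2.9)
  expect_equal(n1$d_N6_N3, 4.6)
  expect_equal(n1$pair_3b3n, "UG")

  ## both O2' distances past the cutoff: extended, never a silent default
  ext <- moveAtom(kturnTemplate("N3"), "-1n", "O2'", c(50, 50, 50))
  expect_equal(classifyConformation(ext)$cls, "extended")

  ## both acceptors bonded and closer than the margin: ambiguous
  amb <- moveAtom(kturnTemplate("N3"), "-1n", "O2'", c(1.1, -2.75, 0))
  cc <- classifyConformation(amb)
  expect_true(all(c(cc$d_O2p_N3, cc$d_O2p_N1) <= 3.5))
  expect_lt(abs(cc$d_O2p_N3 - cc$d_O2p_N1), 0.3)
  expect_equal(cc$cls, "ambiguous")

  ## secondary N6-N3 contradiction downgrades, with both observables kept
  con <- moveAtom(kturnTemplate("N3"), "2n", "N3", c(-1, 8, 0))
  cc2 <- classifyConformation(con)
  expect_equal(cc2$cls, "ambiguous")
  expect_gt(cc2$d_N6_N3, 4)
  expect_match(cc2$reason, "N6-N3")

  ## missing required atom is an explicit error
  broken <- kturnTemplate("N3")
  broken@atoms <- broken@atoms[
    !(broken@atoms$label == "2b" & broken@atoms$elety == "N3"), ]
  expect_error(classifyConformation(broken), "incomplete")
})

test_that("no instance is ever both N3 and N1 across jitter levels", {
  for (jit in c(0, 0.1, 0.3, 0.6)) {
    sims <- c(simulateKTurns("N3", 25, jit, seed = 7 + jit * 100),
              simulateKTurns("N1", 25, jit, seed = 8 + jit * 100))
    cls <- classifyConformation(sims)$cls
    expect_true(all(cls %in% c("N3", "N1", "ambiguous", "extended")))
  }
})

test_that("classification and widths are invariant under rigid motion", {
  set.seed(42)
  kt <- simulateKTurns("N1", 1, 0.1, seed = 5)[[1L]]
  ref <- classifyConformation(kt)
  refW <- helixWidth(kt, c("2b2n", "3b3n", "4b4n"))
  for (i in 1:20) {
    moved <- transformInstance(kt, randomRotation(), runif(3, -100, 100))
    cc <- classifyConformation(moved)
    expect_equal(cc$cls, ref$cls)
    expect_equal(
      unlist(cc[c("d_O2p_N3", "d_O2p_N1", "d_N6_N3", "d_L1_A1n")]),
      unlist(ref[c("d_O2p_N3", "d_O2p_N1", "d_N6_N3", "d_L1_A1n")]),
      tolerance = 1e-9)
    expect_equal(helixWidth(moved, c("2b2n", "3b3n", "4b4n"))$c1c1,
                 refW$c1c1, tolerance = 1e-9)
    expect_equal(bpFamily(moved)$family, "cis WC/WC")
  }
})

test_that("helix widths hit the template targets and flag degenerate input", {
  w3 <- helixWidth(kturnTemplate("N3"), c("2b2n", "3b3n", "4b4n"))
  expect_equal(w3$c1c1, c(8.93, 9.59, 10.55), tolerance = 1e-6)
  w1 <- helixWidth(kturnTemplate("N1"), c("2b2n", "3b3n", "4b4n"))
  expect_equal(w1$c1c1, c(10.17, 11.30, 10.55), tolerance = 1e-6)

  degen <- moveAtom(kturnTemplate("N3"), "2n", "C1'", c(0, -2, 0))
  expect_warning(w <- helixWidth(degen, "2b2n"), "implausible")
  expect_equal(w$c1c1, 0)
  expect_true(w$implausible)
})

test_that("width statistics use the sample SD and report absent SD for n = 1", {
  rec <- data.frame(pair_label = "2b2n", cls = "N3",
                    c1c1 = c(8.9, 9.0, 8.9))
  s <- widthStatistics(rec)
  expect_equal(s$mean, 8.93333333, tolerance = 1e-7)
  expect_equal(s$sd, 0.05773503, tolerance = 1e-7)   # hand-computed n-1 SD
  expect_equal(s$n, 3L)
  expect_equal(attr(s, "sd_estimator"), "sample")

  one <- widthStatistics(data.frame(pair_label = "3b3n", cls = "N1",
                                    c1c1 = 11.2))
  expect_equal(one$mean, 11.2)
  expect_true(is.na(one$sd))

  expect_error(widthStatistics(data.frame()), "no width records")
})

test_that("cis/trans matches the independent torsion-angle oracle", {
  set.seed(77)
  checked <- 0L
  for (i in 1:1000) {
    p <- matrix(runif(12, -10, 10), 4L, 3L, byrow = TRUE)
    ## rows: C1'b, N(gly)b, N(gly)n, C1'n
    mine <- kturnlab:::bpOrientation(p[1, ], p[2, ], p[3, ], p[4, ])
    if (is.na(mine)) next
    tors <- bio3d::torsion.xyz(as.numeric(t(p)), atm.inc = 4)
    if (is.na(tors)) next
    oracle <- if (abs(tors) < 90) "cis" else "trans"
    expect_identical(mine, oracle)
    checked <- checked + 1L
  }
  expect_gt(checked, 990L)
})

test_that("basepair families: canonical G-C is cis WC/WC, A.G is trans Hoogsteen/sugar", {
  gc <- bpFamily(gcPairInstance())
  expect_equal(gc$family, "cis WC/WC")
  expect_equal(gc$n_hbonds, 3L)

  ag <- bpFamily(kturnTemplate("N3"))
  expect_equal(ag$family, "trans Hoogsteen/sugar")
  expect_equal(ag$orientation, "trans")
  expect_equal(ag$edge_b, "Hoogsteen")
  expect_equal(ag$edge_n, "sugar")

  ug <- bpFamily(kturnTemplate("N1"))
  expect_equal(ug$family, "cis WC/WC")

  ## all inter-base distances beyond 4 A: undetermined
  apart <- bpFamily(gcPairInstance(shift_n = 20))
  expect_equal(apart$family, "undetermined")
  expect_equal(apart$n_hbonds, 0L)
  expect_match(apart$reason, "no inter-base")

  ## degrades gracefully when base atoms are absent (only C1' at 4b,4n)
  none <- bpFamily(kturnTemplate("N3"), pairLabel = "4b4n")
  expect_equal(none$family, "undetermined")
  expect_match(none$reason, "absent")
})
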