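TARGETS <- list(
  N3 = c(d_O2p_N3 = 2.9, d_O2p_N1 = 5.1, d_N6_N3 = 2.9, d_L1_A1n = 2.8,
         c2b2n = 8.93, c3b3n = 9.59, c4b4n = 10.55),
  N1 = c(d_O2p_N3 = 5.1, d_O2p_N1 = 2.9, d_N6_N3 = 4.6, d_L1_A1n = 2.8,
         c2b2n = 10.17, c3b3n = 11.30, c4b4n = 10.55)
)

test_that("templates meet every target distance exactly at zero jitter", {
  for (cls in c("N3", "N1")) {
    kt <- simulateKTurns(cls, 1, jitterSd = 0)[[1L]]
    cc <- classifyConformation(kt)
    w <- helixWidth(kt, c("2b2n", "3b3n", "4b4n"))
    got <- c(cc$d_O2p_N3, cc$d_O2p_N1, cc$d_N6_N3, cc$d_L1_A1n, w$c1c1)
    expect_equal(got, unname(TARGETS[[cls]]), tolerance = 1e-6)
    expect_equal(cc$cls, cls)
  }
  ## template hydrogen-bond envelope: bonded contacts under 3.2, broken
  ## ones beyond 4.2/4.5
  n3 <- classifyConformation(kturnTemplate("N3"))
  expect_lte(n3$d_O2p_N3, 3.2); expect_lte(n3$d_N6_N3, 3.2)
  expect_gte(n3$d_O2p_N1, 4.5)
  n1 <- classifyConformation(kturnTemplate("N1"))
  expect_lte(n1$d_O2p_N1, 3.2); expect_gte(n1$d_N6_N3, 4.2)
  expect_gte(n1$d_O2p_N3, 4.5)
})

test_that("identical parameters give byte-identical outputs", {
  a <- simulateKTurns("N3", 3, 0.2, seed = 123)
  b <- simulateKTurns("N3", 3, 0.2, seed = 123)
  expect_identical(lapply(a, slot, "atoms"), lapply(b, slot, "atoms"))

  fa <- tempfile(fileext = ".pdb"); fb <- tempfile(fileext = ".pdb")
  writeKTurnPDB(a, fa); writeKTurnPDB(b, fb)
  expect_identical(readLines(fa), readLines(fb))

  s1 <- simulateAlignment(kturnPopulationFreq("kt7"), 200, seed = 9)
  s2 <- simulateAlignment(kturnPopulationFreq("kt7"), 200, seed = 9)
  expect_identical(as.character(Biostrings::unmasked(s1$aln)),
                   as.character(Biostrings::unmasked(s2$aln)))
  ## and the caller's RNG stream is untouched
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(simulateKTurns("N1", 1, 0.1, seed = 77))
  expect_identical(runif(1), before)
})

test_that("generator/classifier closure: exact recovery at benchmark jitter", {
  sims <- c(simulateKTurns("N3", 30, 0.1, seed = 41),
            simulateKTurns("N1", 30, 0.1, seed = 42))
  cls <- classifyConformation(sims)
  expect_equal(cls$cls, rep(c("N3", "N1"), each = 30))
  ## misclassification surfaces as explicit states at extreme jitter,
  ## never as a silent flip of the generating class
  wild <- classifyConformation(simulateKTurns("N3", 60, 0.4, seed = 43))
  expect_true(all(wild$cls %in% c("N3", "ambiguous", "extended")))
})

test_that("simulated structures round-trip through the structure reader", {
  sims <- simulateKTurns("N1", 2, 0.1, seed = 17)
  f <- tempfile(fileext = ".pdb")
  writeKTurnPDB(sims, f)
  back <- enumerateInstances(loadStructure(f),
                             instanceAnnotation(sims[[1L]], "rt"))
  expect_length(back, 2L)
  for (i in 1:2) {
    orig <- classifyConformation(sims[[i]])
    got <- classifyConformation(back[[i]])
    expect_equal(got$cls, orig$cls)
    expect_equal(got$d_O2p_N1, orig$d_O2p_N1, tolerance = 2e-3)
  }
})

test_that("alignment generator honours the requested distribution", {
  ## degenerate distribution round-trips exactly
  m <- matrix(0, 4, 4, dimnames = list(c("A","C","G","U"), c("A","C","G","U")))
  m["U", "G"] <- 1
  sim <- simulateAlignment(newFreq4x4(m), n = 50, seed = 3)
  fr <- profileAlignment(sim$aln, sim$col3b, sim$col3n)
  expect_equal(pairFractions(fr)["U", "G"], 100)

  ## uniform distribution: every cell within the simultaneous 99% CI
  u <- newFreq4x4(matrix(1 / 16, 4, 4))
  simu <- simulateAlignment(u, n = 16000, seed = 7)
  fru <- profileAlignment(simu$aln, simu$col3b, simu$col3n)
  expect_true(recoveryWithinCI(pairCounts(fru), pairCounts(u)))

  ## substitution noise stays off the 3b/3n columns
  noisy <- simulateAlignment(newFreq4x4(m), n = 40, seed = 5,
                             subRate = 0.3)
  obs <- extractPairs(noisy$aln, noisy$col3b, noisy$col3n)
  expect_true(all(obs$b == "U" & obs$n == "G"))

  bad <- newFreq4x4(matrix(0, 4, 4))
  expect_error(simulateAlignment(bad, n = 10), "normalize")
})

test_that("population profile at published scale recovers the N1-dominant summary", {
  sim <- simulateAlignment(kturnPopulationFreq("kt7"), n = 2722, seed = 19)
  s <- summarizeProfile(profileAlignment(sim$aln, sim$col3b, sim$col3n))
  ## binomial sampling noise at n = 2722 around 99.4% is ~0.15pp; allow 4 SD
  expect_equal(unname(s@fractions["N1"]), 99.4, tolerance = 0.01)
  expect_gt(unname(s@fractions["folds"]), 99)
})

test_that("the synthetic crystal ensemble yields 17 independent N3 copies", {
  d <- file.path(tempdir(), "xtal")
  man <- simulateCrystalSet(d, seed = 11)
  insts <- list()
  for (i in seq_len(nrow(man))) {
    insts <- c(insts, enumerateInstances(
      loadStructure(man$file[i]), readAnnotations(man$annotation[i]),
      source = basename(man$file[i])))
  }
  expect_length(insts, 17L)
  cls <- classifyConformation(insts)
  expect_true(all(cls$cls == "N3"))
  unlink(d, recursive = TRUE)
})
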