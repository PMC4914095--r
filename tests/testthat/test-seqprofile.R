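test_that("the three alignment formats parse to the same rows", {
  rows <- alnRows()
  fa <- readAlignment(writeFastaAln(rows))
  expect_equal(as.character(Biostrings::unmasked(fa)), rows)

  sto <- readAlignment(writeStockholmAln(rows))
  expect_equal(as.character(Biostrings::unmasked(sto)), rows)

  clu <- readAlignment(writeClustalAln(rows))
  expect_equal(as.character(Biostrings::unmasked(clu)), rows)
})

test_that("T normalizes to U and case folds on ingest", {
  f <- writeTemp(c(">s1", "gatGgc", ">s2", "GAT-GT"), ".fa")
  a <- as.character(Biostrings::unmasked(readAlignment(f)))
  expect_equal(unname(a), c("GAUGGC", "GAU-GU"))
  f2 <- writeTemp(c("# STOCKHOLM 1.0", "s1 gatGgc", "//"), ".sto")
  expect_equal(unname(as.character(Biostrings::unmasked(readAlignment(f2)))),
               "GAUGGC")
})

test_that("a ragged FASTA alignment errors naming the offending record", {
  f <- writeTemp(c(">ok1", "GAUGGC", ">short", "GAUG"), ".fa")
  expect_error(readAlignment(f), "short")
})

test_that("pair extraction reads the stated columns and excludes gaps/ambiguity", {
  obs <- extractPairs(c(r1 = "GAUGGC"), 3, 6)
  expect_equal(obs$b, "U")
  expect_equal(obs$n, "C")
  expect_true(obs$included)

  obs2 <- extractPairs(c(a = "GA-GGC", b = "GAUGGN", c = "GAUGGC"), 3, 6)
  expect_equal(obs2$included, c(FALSE, FALSE, TRUE))
  expect_equal(obs2$reason, c("gap", "ambiguous", ""))

  expect_error(extractPairs(c(x = "GAUGGC"), 3, 7), "out of range")
})

test_that("profiles conserve counts and fractions sum to 100% of included", {
  obs <- data.frame(id = as.character(1:10), b = "U", n = "G",
                    included = TRUE, reason = "")
  fr <- profilePairs(obs)
  expect_equal(pairFractions(fr)["U", "G"], 100)
  expect_equal(sum(pairCounts(fr)), 10)

  wc <- data.frame(id = as.character(1:4),
                   b = c("A", "U", "G", "C"), n = c("U", "A", "C", "G"),
                   included = TRUE, reason = "")
  frw <- profilePairs(wc)
  expect_equal(unname(pairFractions(frw)[cbind(wc$b, wc$n)]),
               rep(25, 4))

  mixed <- rbind(obs, data.frame(id = "g", b = "-", n = "G",
                                 included = FALSE, reason = "gap"))
  fm <- profilePairs(mixed)
  expect_equal(sum(pairCounts(fm)) + fm@nExcluded, nrow(mixed))
  expect_equal(sum(pairFractions(fm)), 100, tolerance = 1e-9)
  ## denominator switch counts excluded rows
  expect_equal(sum(pairFractions(fm, denominator = "all")),
               100 * 10 / 11, tolerance = 1e-9)

  expect_error(profilePairs(mixed[11, ]), "empty profile")
})

test_that("profiles are independent of record order", {
  set.seed(1)
  sim <- simulateAlignment(kturnPopulationFreq("sam1"), n = 300, seed = 2)
  rows <- as.character(Biostrings::unmasked(sim$aln))
  f1 <- profilePairs(extractPairs(rows, sim$col3b, sim$col3n))
  f2 <- profilePairs(extractPairs(rev(rows), sim$col3b, sim$col3n))
  expect_identical(pairCounts(f1), pairCounts(f2))
})

test_that("population summaries follow the rule table", {
  tab <- defaultRuleTable()
  m <- matrix(0, 4, 4, dimnames = list(c("A","C","G","U"), c("A","C","G","U")))
  m["U", "G"] <- 100
  s <- summarizeProfile(newFreq4x4(m), tab)
  expect_equal(unname(s@fractions["N1"]), 100)
  expect_equal(unname(s@fractions["folds"]), 100)

  m2 <- m * 0; m2["G", "C"] <- 1
  s2 <- summarizeProfile(newFreq4x4(m2), tab)
  expect_equal(unname(s2@fractions["N3"]), 100)
  expect_equal(unname(s2@fractions["folds"]), 0)

  ## half A.G, half C-G: both cells are N3 in the packaged table
  m3 <- m * 0; m3["A", "G"] <- 50; m3["C", "G"] <- 50
  s3 <- summarizeProfile(newFreq4x4(m3), tab)
  expect_equal(unname(s3@fractions["N3"]), 100)
  expect_equal(unname(s3@fractions["folds"]), 50)  # C-G does not fold
})

test_that("summarize equals brute-force per-sequence aggregation", {
  tab <- defaultRuleTable()
  sim <- simulateAlignment(kturnPopulationFreq("u4"), n = 400, seed = 31)
  obs <- extractPairs(sim$aln, sim$col3b, sim$col3n)
  s <- summarizeProfile(profilePairs(obs), tab)

  inc <- obs[obs$included, ]
  conf <- predictConformation(inc$b, inc$n, tab)
  fold <- predictFolding(inc$b, inc$n)
  expect_equal(unname(s@fractions["N3"]), 100 * mean(conf == "N3"))
  expect_equal(unname(s@fractions["N1"]), 100 * mean(conf == "N1"))
  expect_equal(unname(s@fractions["unknown"]),
               100 * mean(conf == "unknown"))
  expect_equal(unname(s@fractions["folds"]), 100 * mean(fold == "yes"))
  expect_equal(unname(s@fractions["N3"] + s@fractions["N1"] +
                      s@fractions["unknown"]), 100)
})

test_that("the rendered report labels the larger fraction of each bar", {
  m <- matrix(0, 4, 4, dimnames = list(c("A","C","G","U"), c("A","C","G","U")))
  m["U", "G"] <- 9; m["G", "C"] <- 1
  s <- summarizeProfile(newFreq4x4(m))
  lines <- renderSummary(s)
  expect_length(lines, 3L)
  expect_match(lines[2L], "N1 90.0%")
  expect_match(lines[3L], "folds 90.0%")
})

test_that("frequency TSV reader round-trips the packaged populations", {
  fr <- kturnPopulationFreq("kt7")
  expect_s4_class(fr, "Freq4x4")
  expect_equal(pairFractions(fr)["U", "G"], 92.06)
  expect_equal(sum(pairCounts(fr)), 100)
  expect_error(readFreq(writeTemp(c("3b\tA\tC", "A\t1\t2"), ".tsv")),
               "4x4")
})
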