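test_that("the three measures reproduce hand arithmetic on tiny datasets", {
  # two replicates of one individual each: blocks {0.2, 0.4} and {0.6}
  ds <- handDataset(list(list(c(0.2, 0.4)), list(0.6)))
  expect_equal(lengthAR(ds, 1), 0.4)          # 1.2 / 3
  expect_equal(lengthPW(ds, 1), 0.45)         # mean(0.3, 0.6)
  expect_equal(lengthAR(ds, 1, from = "blocks"), 0.4)

  # a single replicate: population-wise equals across-replicate
  one <- handDataset(list(list(c(0.2, 0.4), 0.6)))
  expect_equal(lengthPW(one, 1), lengthAR(one, 1))
  # two individuals in one replicate: individual-wise mean of means
  expect_equal(lengthIW(one, 1), 0.45)

  # single block anywhere
  single <- handDataset(list(list(0.3)))
  expect_equal(lengthAR(single, 1), 0.3)
  expect_equal(lengthIW(single, 1), 0.3)

  # one block per individual: equal weights, IW == AR
  eq <- handDataset(list(list(0.1, 0.5), list(0.3, 0.7)))
  expect_equal(lengthIW(eq, 1), lengthAR(eq, 1))
})

test_that("blockless units are excluded by default and zeroed on request", {
  # two replicates of two individuals; only one individual carries a block
  ds <- handDataset(list(list(0.5, numeric(0)),
                         list(numeric(0), numeric(0))))
  pw <- lengthPW(ds, 1, details = TRUE)
  expect_equal(pw$value, 0.5)
  expect_equal(pw$nExcluded, 1L)
  expect_equal(lengthPW(ds, 1, zeroBlockPolicy = "zero"), 0.25)

  iw <- lengthIW(ds, 1, details = TRUE)
  expect_equal(iw$value, 0.5)
  expect_equal(iw$nExcluded, 3L)
  expect_equal(lengthIW(ds, 1, zeroBlockPolicy = "zero"), 0.125)

  empty <- handDataset(list(list(numeric(0)), list(numeric(0))))
  expect_warning(v <- lengthAR(empty, 1), "no IBD block")
  expect_true(is.na(v))
  expect_warning(lengthPW(empty, 1), "blockless")
})

test_that("the across-replicate measure is the ratio of pooled sums", {
  set.seed(14)
  lists <- lapply(1:6, function(r)
    lapply(1:4, function(i) stats::runif(stats::rpois(1, 2), 0.01, 0.5)))
  ds <- handDataset(lists)
  gs <- generationStats(ds)
  expect_identical(lengthAR(ds, 1), sum(gs$sumD) / sum(gs$sumK))
  mom <- empiricalMoments(ds, 1)
  expect_equal(lengthAR(ds, 1), expectedLRatio(mom$ED, mom$EK),
               tolerance = 1e-14)
})

test_that("theoretical formulas match hand substitution", {
  expect_equal(expectedD(1, 1), 0)
  expect_equal(expectedD(0, 2.5), 2.5)
  expect_equal(expectedD(0.2, 1), 0.8)

  expect_equal(expectedK(1, 0, 1), 0)
  expect_equal(expectedK(0, 0, 1), 1)     # one chromosome-spanning block
  expect_equal(expectedK(0.5, 1, 1), 1)

  expect_equal(expectedLFinite(0, 0, 3), 3)
  expect_equal(expectedLFinite(0.5, 1, 1), 0.5)

  expect_equal(expectedLStam(0.5, 1), 1)
  expect_equal(expectedLStam(1, 2), 0)

  expect_equal(expectedLRatio(0.5, 2), 0.25)
  expect_equal(expectedLRatio(1, 1), 1)
  expect_warning(v <- expectedLRatio(1, 0), "EK = 0")
  expect_true(is.na(v))
  expect_warning(expectedLStam(0.5, 0), "EZ = 0")
  expect_error(expectedD(1.2, 1), "\\[0, 1\\]")
})

test_that("the finite-length prediction is bounded by the stationary one and
           converges to it as l grows", {
  set.seed(8)
  for (i in 1:50) {
    EH <- stats::runif(1, 0, 0.99)
    EZ <- stats::runif(1, 0.05, 5)
    l <- stats::runif(1, 0.2, 5)
    expect_lt(expectedLFinite(EH, EZ, l), expectedLStam(EH, EZ))
  }
  expect_equal(expectedLFinite(0.3, 2, 1e8), expectedLStam(0.3, 2),
               tolerance = 1e-6)
})

test_that("empirical moments recover degenerate regimes", {
  rs <- runReplicates(simParams(popSize = 8, nGenerations = 1,
                                nReplicates = 50, seed = 3,
                                recordGenerations = 1))
  m0 <- empiricalMoments(rs, 0)
  expect_equal(c(m0$EH, m0$EZ, m0$ED, m0$EK), c(1, 0, 0, 0))
  m1 <- empiricalMoments(rs, 1)
  expect_equal(c(m1$EH, m1$EZ, m1$ED, m1$EK), c(1, 0, 0, 0))

  # a fully fixed pair: one full-length block
  fixed <- handDataset(list(list(1, 1)))
  expect_equal(lengthAR(fixed, 1), 1)
  mom <- empiricalMoments(fixed, 1)
  expect_equal(mom$EH, 0)
  expect_equal(mom$EK, 1)
  expect_equal(mom$ED, 1)
})

test_that("the estimate report assembles all quantities consistently", {
  rs <- runReplicates(simParams(popSize = 10, nGenerations = 20,
                                nReplicates = 300, seed = 6,
                                recordGenerations = 20))
  rep <- estimateReport(rs, generations = c(0, 10, 20), bootstrapB = 200)
  expect_equal(rep$generation, c(0, 10, 20))
  expect_true(is.na(rep$L_AR[1]))
  expect_equal(rep$L_AR[2], lengthAR(rs, 10))
  expect_equal(rep$L_PW[3], lengthPW(rs, 20))
  expect_equal(rep$L_IW[3], lengthIW(rs, 20))
  expect_equal(rep$EL_pred[2],
               expectedLFinite(rep$EH_hat[2], rep$EZ_hat[2], 1))
  expect_true(all(rep$se_AR[-1] > 0))
  expect_true(all(rep$nExcludedIndividuals >= 0))
})
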