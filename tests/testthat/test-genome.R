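test_that("founder mosaics are single-segment and reject bad lengths", {
  f <- founderMosaic(7L, 1.0)
  expect_equal(chromLength(f), 1.0)
  expect_equal(f@origins, 7L)
  expect_length(junctionPositions(f), 0)

  f2 <- founderMosaic(3L, 2.5)
  expect_equal(segmentTable(f2),
               data.frame(start = 0, end = 2.5, origin = 3L))

  z <- founderMosaic(1L, 0)
  expect_equal(chromLength(z), 0)
  expect_length(z@origins, 0)

  expect_error(founderMosaic(1L, -1), "non-negative")
})

test_that("crossover draws follow the no-interference model", {
  expect_identical(drawCrossovers(0), numeric(0))
  set.seed(11)
  for (i in 1:20) {
    x <- drawCrossovers(2)
    expect_true(all(x > 0 & x < 2))
    expect_true(!is.unsorted(x, strictly = TRUE))
  }
  set.seed(12)
  counts <- vapply(1:20000, function(i) length(drawCrossovers(1)), integer(1))
  # Poisson(1): mean 1, zero-class mass exp(-1); 4 SE bands
  expect_lt(abs(mean(counts) - 1), 4 / sqrt(20000))
  p0 <- exp(-1)
  expect_lt(abs(mean(counts == 0) - p0),
            4 * sqrt(p0 * (1 - p0) / 20000))
})

test_that("normalization merges invisible breakpoints and is idempotent", {
  m <- normalizeMosaic(data.frame(start = c(0, 0.5), end = c(0.5, 1),
                                  origin = c(1L, 1L)))
  expect_equal(m@breakpoints, c(0, 1))
  expect_equal(m@origins, 1L)

  keep <- data.frame(start = c(0, 0.5), end = c(0.5, 1), origin = c(1L, 2L))
  m2 <- normalizeMosaic(keep)
  expect_equal(segmentTable(m2), keep)
  expect_equal(normalizeMosaic(segmentTable(m2)), m2)

  m3 <- normalizeMosaic(data.frame(start = c(0, 0.2, 0.6),
                                   end = c(0.2, 0.6, 1),
                                   origin = c(1L, 1L, 2L)))
  expect_equal(m3@breakpoints, c(0, 0.6, 1))
  expect_equal(m3@origins, c(1L, 2L))

  expect_error(normalizeMosaic(data.frame(start = c(0, 0.4),
                                          end = c(0.5, 1),
                                          origin = 1:2)), "gaps|overlap")
  expect_error(normalizeMosaic(data.frame(start = 0.1, end = 1,
                                          origin = 1L)), "start at 0")
})

test_that("a fully homozygous parent always yields the parental gamete", {
  p <- individual(founderMosaic(1L, 1), founderMosaic(1L, 1))
  for (s in 1:5) {
    set.seed(s)
    g <- meiosis(p)
    expect_equal(g@breakpoints, c(0, 1))
    expect_equal(g@origins, 1L)
  }
})

test_that("gametes conserve length, inherit parental origins, and junctions
           never exceed crossovers", {
  set.seed(42)
  for (i in 1:200) {
    l <- sample(c(0.5, 1, 2), 1)
    p <- individual(randomMosaic(l, 4, 1:3), randomMosaic(l, 4, 3:6))
    det <- meiosis(p, detailed = TRUE)
    g <- det$gamete
    st <- segmentTable(g)
    expect_equal(sum(st$end - st$start), l, tolerance = 1e-12)
    expect_equal(g@breakpoints[length(g@breakpoints)], l)
    expect_true(all(g@origins %in% c(p@maternal@origins, p@paternal@origins)))
    # a gamete's junctions are crossovers of this meiosis or junctions
    # copied from a parental homologue
    inherited <- length(junctionPositions(p@maternal)) +
      length(junctionPositions(p@paternal))
    expect_lte(length(junctionPositions(g)),
               length(det$crossovers) + inherited)
    expect_true(all(junctionPositions(g) %in%
                      c(det$crossovers, junctionPositions(p@maternal),
                        junctionPositions(p@paternal))))
    expect_true(validObject(g))
  }
})

test_that("meiosis from a fully heterozygous parent transmits each homologue
           equally and junction counts match crossover counts", {
  p <- individual(founderMosaic(1L, 1), founderMosaic(2L, 1))
  set.seed(7)
  n <- 4000
  fracA <- numeric(n)
  nj <- integer(n)
  for (i in seq_len(n)) {
    g <- meiosis(p)
    st <- segmentTable(g)
    fracA[i] <- sum((st$end - st$start)[st$origin == 1L])
    nj[i] <- length(junctionPositions(g))
  }
  # every crossover is visible here, so junction count is Poisson(1)
  expect_lt(abs(mean(nj) - 1), 4 / sqrt(n))
  # fair starting coin: half the genome comes from each homologue on average
  expect_lt(abs(mean(fracA) - 0.5), 4 * stats::sd(fracA) / sqrt(n))
})
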