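test_that("the worked-example pair has one relaxed and two strict blocks", {
  fp <- figPair()
  rel <- relaxedSegments(fp)
  expect_equal(nrow(rel), 1L)
  expect_equal(rel$start, 0)
  expect_equal(rel$end, 0.8)

  str <- strictSegments(fp)
  expect_equal(nrow(str), 2L)
  expect_equal(str$start, c(0, 0.5))
  expect_equal(str$end, c(0.5, 0.8))
  expect_equal(str$origin, c(1L, 2L))

  jn <- classifyJunctions(fp)
  # junctions at 0.5 on both homologues: internal, inside the IBD tract;
  # junction at 0.8 on homologue 1: external
  expect_equal(nrow(jn), 3L)
  at05 <- jn[jn$position == 0.5, ]
  expect_equal(sort(at05$carrier), c(0L, 1L))
  expect_true(all(at05$kind == "internal"))
  expect_true(all(at05$context == "within-IBD"))
  at08 <- jn[jn$position == 0.8, ]
  expect_equal(at08$carrier, 1L)
  expect_equal(at08$kind, "external")

  s <- summarizeIBD(fp)
  expect_equal(s$d, 0.8)
  expect_equal(s$k, 1L)
  expect_equal(s$h, 0.2)
  expect_equal(s$zCount, 1L)
  expect_equal(s$ibdTips, 1L)
  expect_equal(2 * s$k, s$zCount + s$ibdTips)
})

test_that("degenerate pairs: founders, full identity, self-pair", {
  founder <- individual(founderMosaic(1L, 1), founderMosaic(2L, 1))
  expect_equal(nrow(relaxedSegments(founder)), 0L)
  expect_equal(nrow(strictSegments(founder)), 0L)
  expect_equal(nrow(classifyJunctions(founder)), 0L)
  s <- summarizeIBD(founder)
  expect_equal(unlist(s[c("d", "k", "h", "zCount", "ibdTips")]),
               c(d = 0, k = 0, h = 1, zCount = 0, ibdTips = 0))

  same <- individual(founderMosaic(5L, 1), founderMosaic(5L, 1))
  s2 <- summarizeIBD(same)
  expect_equal(s2$d, 1)
  expect_equal(s2$k, 1L)
  expect_equal(s2$ibdTips, 2L)
  expect_equal(s2$zCount, 0L)
  expect_equal(2 * s2$k, s2$zCount + s2$ibdTips)

  m <- mosaic(c(0, 0.4, 1), c(1L, 2L))
  self <- individual(m, m)
  expect_equal(relaxedSegments(self)$end, 1)
  str <- strictSegments(self)
  expect_equal(str$start, c(0, 0.4))
  expect_equal(str$end, c(0.4, 1))
  jn <- classifyJunctions(self)
  expect_true(all(jn$kind == "internal" & jn$context == "within-IBD"))
})

test_that("zero-length chromosomes reject the non-IBD proportion", {
  z <- individual(founderMosaic(1L, 0), founderMosaic(2L, 0))
  expect_error(summarizeIBD(z), "zero-length")
})

test_that("homologue length mismatch is a structural error", {
  expect_error(individual(founderMosaic(1L, 1), founderMosaic(2L, 2)),
               "mismatch")
})

test_that("strict blocks refine relaxed blocks and the edge identity holds
           on random pairs", {
  set.seed(99)
  for (i in 1:80) {
    ind <- individual(randomMosaic(1, 5, 1:4), randomMosaic(1, 5, 1:4))
    rel <- relaxedSegments(ind)
    str <- strictSegments(ind)
    expect_equal(sum(str$length), sum(rel$length), tolerance = 1e-12)
    expect_gte(nrow(str), nrow(rel))
    # strict blocks tile the relaxed ones as point sets
    if (nrow(rel) > 0) {
      expect_true(all(vapply(seq_len(nrow(str)), function(j)
        any(rel$start <= str$start[j] & str$end[j] <= rel$end[j]),
        logical(1))))
    }
    s <- summarizeIBD(ind)
    expect_equal(2 * s$k, s$zCount + s$ibdTips)
    expect_equal(s$strictLength, s$d, tolerance = 1e-12)
    expect_gte(s$strictCount, s$k)
  }
})

test_that("extraction is symmetric in the two homologues", {
  set.seed(123)
  for (i in 1:25) {
    a <- randomMosaic(1, 5, 1:4)
    b <- randomMosaic(1, 5, 1:4)
    s1 <- summarizeIBD(individual(a, b))
    s2 <- summarizeIBD(individual(b, a))
    expect_equal(s1, s2)
    j1 <- classifyJunctions(individual(a, b))
    j2 <- classifyJunctions(individual(b, a))
    expect_equal(j1$position, j2$position)
    expect_equal(j1$kind, j2$kind)
    expect_equal(j1$carrier, 1L - j2$carrier)
  }
})

test_that("interval extraction agrees with a grid-based caller", {
  set.seed(7)
  step <- 1e-4
  for (i in 1:25) {
    ind <- individual(randomMosaic(1, 6, 1:4), randomMosaic(1, 6, 1:4))
    rel <- relaxedSegments(ind)
    grid <- gridRelaxed(ind, step)
    expect_equal(nrow(rel), nrow(grid))
    if (nrow(rel) > 0) {
      expect_true(all(abs(rel$start - grid$start) <= step))
      expect_true(all(abs(rel$end - grid$end) <= step))
    }
  }
})
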