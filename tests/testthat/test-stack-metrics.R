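rand_binary <- function(n, nr = 15, nc = 15, p = 0.4, land_na = TRUE) {
  lapply(seq_len(n), function(i) {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    if (land_na) m[1, 1] <- NA_integer_
    m
  })
}

test_that("richness stacking equals the brute-force cellwise sum", {
  set.seed(2)
  maps <- rand_binary(50)
  r <- stack_richness(maps)
  # brute-force oracle, cell by cell
  for (cell in c(2, 77, 225)) {
    expect_equal(r[cell], sum(vapply(maps, `[[`, numeric(1), cell)))
  }
  expect_true(all(r[!is.na(r)] >= 0 & r[!is.na(r)] <= 50))

  # all suitable / none suitable
  ones <- lapply(1:7, function(i) matrix(1, 4, 4))
  expect_true(all(stack_richness(ones) == 7))
  zeros <- lapply(1:7, function(i) matrix(0, 4, 4))
  expect_true(all(stack_richness(zeros) == 0))

  # double-counting identity: sum over cells = sum over species of
  # suitable-cell counts, exact
  expect_equal(sum(r, na.rm = TRUE),
               sum(vapply(maps, function(m) sum(m, na.rm = TRUE), numeric(1))))

  # monotonicity: adding a species never decreases richness
  r2 <- stack_richness(c(maps, rand_binary(1)))
  expect_true(all(r2[!is.na(r2)] >= r[!is.na(r)]))

  expect_error(stack_richness(list(matrix(1, 2, 2), matrix(1, 3, 3))), "grid")
})

test_that("hotspot cut-off arithmetic and strictness match the rule", {
  set.seed(3)
  rich <- matrix(rpois(400, 800), 20, 20)
  rich[1, 1] <- NA
  h <- hotspot_map(rich, M = 9701, f = 0.10)
  expect_equal(h$cutoff, 970) # floor(0.10 x 9,701)
  # strict exceedance at the boundary
  rb <- matrix(c(971, 970, 0, 0), 2, 2)
  hb <- hotspot_map(rb, M = 9701, f = 0.10)
  expect_equal(as.integer(hb$map[1, 1]), 1L)
  expect_equal(as.integer(hb$map[2, 1]), 0L)

  # land fraction equals the counting oracle
  land <- !is.na(rich)
  expect_equal(h$land_fraction, sum(rich[land] > 970) / sum(land))

  # hotspot monotonicity in f: larger fraction, nested hotspot set
  h05 <- hotspot_map(rich, 9701, 0.05)
  h15 <- hotspot_map(rich, 9701, 0.15)
  expect_true(all(h15$map[land] <= h$map[land]))
  expect_true(all(h$map[land] <= h05$map[land]))

  # a fixed cutoff overrides f (future maps reuse the current cut-off)
  hfix <- hotspot_map(rich, 9701, 0.10, cutoff = 970)
  expect_identical(hfix$map, h$map)
  expect_error(hotspot_map(rich, 0), "M")
})

test_that("change maps difference and mask as specified", {
  cur <- matrix(c(100, 0, 50, 10), 2, 2)
  fut <- matrix(c(150, 5, 50, 0), 2, 2)
  ch <- change_maps(cur, fut)
  expect_equal(ch$absolute, fut - cur)
  expect_equal(ch$proportional[1, 1], 0.5)
  expect_true(is.na(ch$proportional[2, 1])) # current 0 -> masked
  expect_equal(ch$proportional[1, 2], 0)
  ident <- change_maps(cur, cur)
  expect_true(all(ident$absolute == 0))
  expect_equal(ident$proportional[1, 1], 0)
})

test_that("turnover is the Jaccard dissimilarity of suitable-species sets", {
  # identical non-empty sets -> 0; disjoint -> 1; hand Jaccard for overlap
  a <- matrix(1, 1, 1); z <- matrix(0, 1, 1)
  spA <- list(a, a, a, z)          # current: {1,2,3}
  spB_same <- list(a, a, a, z)
  spB_disj <- list(z, z, z, a)     # future: {4}
  expect_equal(as.numeric(turnover(spA, spB_same)[1, 1]), 0)
  expect_equal(as.numeric(turnover(spA, spB_disj)[1, 1]), 1)
  # A = {a,b,c}, B = {b,c,d}: 1 - 2/4 = 0.5
  spB <- list(z, a, a, a)
  expect_equal(as.numeric(turnover(spA, spB)[1, 1]), 0.5)
  # both sets empty -> 0 by decision
  expect_equal(as.numeric(turnover(list(z), list(z))[1, 1]), 0)

  # symmetry and range on random stacks, against a per-cell set oracle
  set.seed(9)
  curM <- rand_binary(12)
  futM <- rand_binary(12)
  tv <- turnover(curM, futM)
  expect_equal(tv, turnover(futM, curM)) # exact symmetry
  land <- !is.na(tv)
  expect_true(all(tv[land] >= 0 & tv[land] <= 1))
  for (cell in c(3, 50, 120)) {
    A <- which(vapply(curM, `[[`, numeric(1), cell) == 1)
    B <- which(vapply(futM, `[[`, numeric(1), cell) == 1)
    expected <- if (!length(union(A, B))) 0 else {
      1 - length(intersect(A, B)) / length(union(A, B))
    }
    expect_equal(tv[cell], expected)
  }

  # the alternative rate index shares both endpoints
  expect_equal(as.numeric(turnover(spA, spB_same, method = "rate")[1, 1]), 0)
  expect_equal(as.numeric(turnover(spA, spB_disj, method = "rate")[1, 1]), 1)
})

test_that("CV map is sd/mean with the n-1 denominator, masked at zero mean", {
  m1 <- matrix(c(100, 0, 3), 1, 3)
  m2 <- matrix(c(200, 0, 3), 1, 3)
  cv <- cv_map(list(m1, m2))
  expect_equal(cv[1, 1], sd(c(100, 200)) / 150, tolerance = 1e-9)
  expect_equal(round(cv[1, 1], 4), 0.4714)
  expect_true(is.na(cv[1, 2])) # all-zero cell masked
  expect_equal(cv[1, 3], 0)    # identical members -> 0

  set.seed(4)
  members <- lapply(1:5, function(i) matrix(rpois(100, 20), 10, 10))
  cvr <- cv_map(members)
  vals <- vapply(members, `[[`, numeric(1), 55)
  expect_equal(cvr[55], sd(vals) / mean(vals), tolerance = 1e-9)
  expect_error(cv_map(members[1]), ">= 2")
})

test_that("the continental filter only removes suitability", {
  cur <- test_world()$current
  land <- cur$land
  bin <- matrix(NA_integer_, cur$nrows, cur$ncols)
  bin[land] <- rbinom(sum(land), 1, 0.5)
  labels <- sort(unique(cur$continent[land]))
  # allowed everywhere: unchanged
  expect_identical(continental_filter(bin, labels, cur$continent), bin)
  # allowed on one continent: zero elsewhere, never increases
  f1 <- continental_filter(bin, labels[1], cur$continent)
  expect_true(all(f1[land] <= bin[land]))
  expect_true(all(f1[land & cur$continent != labels[1]] == 0))
  expect_error(continental_filter(bin, integer(0), cur$continent), "empty")
})

test_that("hotspot persistence is the retained-cell percentage", {
  mk <- function(v) {
    structure(list(map = matrix(v, 2, 2), cutoff = 10), class = "hotspot_result")
  }
  cur <- mk(c(1, 1, 0, 0))
  expect_equal(hotspot_persistence(cur, mk(c(1, 1, 1, 0))), 100)
  expect_equal(hotspot_persistence(cur, mk(c(0, 0, 1, 1))), 0)
  expect_equal(hotspot_persistence(cur, mk(c(1, 0, 0, 1))), 50)
  # random pair matches the counting oracle
  set.seed(11)
  a <- rbinom(400, 1, 0.3); b <- rbinom(400, 1, 0.3)
  ha <- structure(list(map = matrix(a, 20, 20), cutoff = 5),
                  class = "hotspot_result")
  hb <- structure(list(map = matrix(b, 20, 20), cutoff = 5),
                  class = "hotspot_result")
  expect_equal(hotspot_persistence(ha, hb), 100 * sum(a & b) / sum(a))
  expect_error(hotspot_persistence(mk(c(0, 0, 0, 0)), mk(c(1, 0, 0, 0))),
               "persistence")
})
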