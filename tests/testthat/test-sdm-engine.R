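test_that("collinearity screen reports pairs and honours the strict threshold", {
  cur <- test_world()$current
  # a layer against itself: |r| = 1, fail
  res <- collinearity_screen(cur, c("temp_mean", "temp_mean", "soil_ph"))
  expect_false(res$pass)
  expect_true(any(abs(res$offending$r) == 1))

  # independent noise layers pass
  res2 <- collinearity_screen(cur, c("precip_seasonality", "soil_ph",
                                     "landuse_natural_fraction"))
  expect_true(res2$pass)

  # exceedance is strict: a pair exactly at the threshold passes
  pairs <- collinearity_screen(cur, predictor_sets()$set1)$pairs
  rmax <- max(abs(pairs$r))
  at <- collinearity_screen(cur, predictor_sets()$set1, max_abs_r = rmax)
  expect_true(at$pass)
  below <- collinearity_screen(cur, predictor_sets()$set1,
                               max_abs_r = rmax - 1e-12)
  expect_false(below$pass)

  # constant layer flagged as failure with a reason
  const <- cur
  const$layers$soil_ph[] <- 5
  res3 <- collinearity_screen(const, c("temp_mean", "soil_ph"))
  expect_false(res3$pass)
  expect_match(res3$reason, "constant")
})

test_that("spatial blocks are a median-split 2x2 partition", {
  # 4 points at 4 distinct quadrant corners: one per block
  pts <- data.frame(row = c(1, 1, 9, 9), col = c(1, 9, 1, 9))
  bl <- make_blocks(pts)
  expect_setequal(as.integer(bl), 1:4)

  # every point is in exactly one block; counting oracle on uniform points
  set.seed(5)
  pts2 <- data.frame(row = runif(1000, 0, 100), col = runif(1000, 0, 100))
  bl2 <- make_blocks(pts2)
  expect_length(bl2, 1000)
  expect_true(all(bl2 %in% 1:4))
  counts <- table(bl2)
  oracle <- table(1L + 2L * (pts2$row > median(pts2$row)) +
                    (pts2$col > median(pts2$col)))
  expect_equal(as.integer(counts), as.integer(oracle))
  expect_true(all(abs(counts - 250) <= 30))

  # a point exactly on both medians goes to the lower-index block
  pts3 <- data.frame(row = c(1, 1, 9, 9, 5), col = c(1, 9, 1, 9, 5))
  bl3 <- make_blocks(pts3)
  expect_equal(bl3[5], 1L)

  expect_error(make_blocks(pts[1:3, ]), ">= 4")
  expect_error(make_blocks(data.frame(row = rep(1, 10), col = rep(1, 10))),
               "empty")
})

test_that("Boyce index endpoints and symmetry behave as a rank statistic", {
  set.seed(1)
  bg <- seq(0, 1, length.out = 1000)

  # presences from the top of a strictly increasing gradient: index near 1
  top <- vapply(1:20, function(s) {
    set.seed(s)
    pres <- sample(bg, 200, replace = TRUE, prob = bg^3)
    boyce_index(pres, bg)$index
  }, numeric(1))
  expect_gt(mean(top), 0.9)

  # presences independent of suitability: index near 0 over seeds
  rnd <- vapply(1:20, function(s) {
    set.seed(s)
    boyce_index(runif(100), runif(1000))$index
  }, numeric(1))
  expect_lt(abs(mean(rnd)), 0.1)

  # antitone symmetry: reversing the prediction scale flips the sign,
  # checked against a hand-coded Spearman oracle on the P/E ratios
  set.seed(3)
  pres <- sample(bg, 150, replace = TRUE, prob = bg^2)
  b <- boyce_index(pres, bg)
  neg <- boyce_index(1 - pres, 1 - bg)
  expect_equal(neg$index, -b$index, tolerance = 0.05)
  spearman_oracle <- function(curve) {
    rf <- rank(curve$F)
    rm_ <- rank(curve$midpoint)
    sum((rf - mean(rf)) * (rm_ - mean(rm_))) /
      sqrt(sum((rf - mean(rf))^2) * sum((rm_ - mean(rm_))^2))
  }
  expect_equal(b$index, spearman_oracle(b$curve), tolerance = 1e-12)

  # near-invariance under strictly monotone transforms (x -> x^3): with
  # fixed-width windows the class partition moves with the scale, so
  # invariance is approximate, not exact
  b3 <- boyce_index(pres^3, bg^3)
  expect_equal(b3$index, b$index, tolerance = 0.15)

  # curve bookkeeping: E > 0 on every retained window, F = P/E
  expect_true(all(b$curve$E > 0))
  expect_equal(b$curve$F, b$curve$P / b$curve$E)

  # structurally undefined cases raise the dedicated condition
  expect_error(boyce_index(rep(0.5, 10), rep(0.5, 100)),
               class = "boyce_undefined")
  expect_error(boyce_index(numeric(0), bg), ">= 1")
  expect_error(boyce_index(0.5, runif(5)), ">= 10")
  expect_error(boyce_index(c(0.5, 1.2), bg), "within")
})

test_that("model fits are seeded, clamped and reject singular designs", {
  cal <- test_calibration()
  pv <- predictor_sets()$set1
  for (alg in c("rf", "brt")) {
    m1 <- fit_sdm(alg, cal$pres, cal$pa, pv, seed = 11)
    m2 <- fit_sdm(alg, cal$pres, cal$pa, pv, seed = 11)
    env <- cell_env(cal$cur, pv)[1:200, ]
    expect_identical(predict(m1, env), predict(m2, env))
    expect_true(all(predict(m1, env) >= 0 & predict(m1, env) <= 1))
  }
  # constant predictor: error names the predictor
  pres_bad <- cal$pres
  pres_bad$records$soil_ph <- 1
  pa_bad <- cal$pa
  pa_bad$records$soil_ph <- 1
  expect_error(
    suppressWarnings(fit_sdm("glm", pres_bad, pa_bad, pv, seed = 1)),
    "soil_ph"
  )
})

test_that("a fitted model recovers a temperature-only niche", {
  cur <- test_world()$current
  eff <- test_effort(cur)
  # niche effectively one-dimensional: huge breadth on the second variable
  nc <- default_niche_config()
  nc$variables <- c("temp_mean", "soil_ph")
  nc$sigma_sd_range <- c(0.5, 0.5)
  sp <- make_species(21, cur, 1, nc)[[1]]
  sp$niche$sigma[2] <- 1e6
  sp$suitability <- true_suitability(sp, cur)
  sp$suitability[land_cells(cur)] <-
    sp$suitability[land_cells(cur)] / max(sp$suitability, na.rm = TRUE)
  occ <- sample_occurrences(21, sp, eff, cur)
  prep <- prepare_occurrences(occ, climatic_vars("set1"), seed = 21)
  expect_true(prep$accepted)
  pres <- prep$occ
  cells <- cell_index(cur, pres$records$row, pres$records$col)
  sre <- fit_sre(pres$records[climatic_vars("set1")])
  pa <- sample_pa(sre, cur, eff, nrow(pres$records), cells, seed = 21,
                  species_id = sp$id)
  m <- suppressWarnings(
    fit_sdm("glm", pres, pa, predictor_sets()$set1, seed = 21)
  )
  li <- land_cells(cur)
  fitted <- predict_raster(m, cur)
  expect_gt(cor(fitted[li], sp$suitability[li], method = "spearman"), 0.7)
})

test_that("block cross-validation visits every fold and nulls score near zero", {
  cal <- test_calibration()
  pv <- predictor_sets()$set1
  cv <- suppressWarnings(
    cross_validate("glm", cal$pres, cal$pa, pv, cal$blocks, cal$cur, seed = 7)
  )
  expect_length(cv$fold_boyce, 4) # each block held out exactly once
  expect_equal(cv$cv_boyce, mean(cv$fold_boyce, na.rm = TRUE))

  # permutation null: shuffle presence/PA labels; signal disappears
  np <- nrow(cal$pres$records)
  all_rec <- rbind(cal$pres$records, cal$pa$records)
  nulls <- vapply(1:3, function(s) {
    set.seed(s)
    idx <- sample(nrow(all_rec))
    pres_s <- occurrence_set(all_rec[idx[1:np], , drop = FALSE],
                             "null", "env_filtered")
    pa_s <- list(records = all_rec[idx[(np + 1):(2 * np)], , drop = FALSE])
    blocks_s <- make_blocks(rbind(pres_s$records[c("row", "col")],
                                  pa_s$records[c("row", "col")]))
    suppressWarnings(
      cross_validate("glm", pres_s, pa_s, pv, blocks_s, cal$cur,
                     seed = s)$cv_boyce
    )
  }, numeric(1))
  expect_lt(abs(mean(nulls, na.rm = TRUE)), 0.35)
})

test_that("a strong-signal species scores cv_boyce > 0.6 for most algorithms", {
  cal <- test_calibration()
  pv <- predictor_sets()$set1
  ms <- suppressWarnings(lapply(c("glm", "gam", "rf", "brt"), function(a) {
    fit_cv_sdm(a, cal$pres, cal$pa, pv, cal$blocks, cal$cur, seed = 7)
  }))
  cvs <- vapply(ms, function(m) m$cv_boyce, numeric(1))
  expect_true(all(is.finite(cvs)))
  expect_true(all(cvs >= -1 & cvs <= 1))
  expect_gte(sum(cvs > 0.6), 3) # 3 of the 4 families on this benchmark
})
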