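test_that("world generation is seed-deterministic and respects shared structure", {
  w1 <- make_world(7, c(30, 30))
  w2 <- make_world(7, c(30, 30))
  expect_identical(w1$current$layers, w2$current$layers)
  expect_identical(w1$severe_r1$layers, w2$severe_r1$layers)

  # soil pH has no future scenarios
  for (tag in c("mild_r1", "mild_r2", "severe_r1", "severe_r2")) {
    expect_identical(w1[[tag]]$layers$soil_ph, w1$current$layers$soil_ph)
    expect_identical(w1[[tag]]$land, w1$current$land)
    expect_identical(w1[[tag]]$continent, w1$current$continent)
  }

  # invariants: finite layers on land, land-use fraction in [0,1],
  # >= 2 continents
  land <- w1$current$land
  for (ly in w1$current$layers) expect_true(all(is.finite(ly[land])))
  lu <- w1$current$layers$landuse_natural_fraction[land]
  expect_true(all(lu >= 0 & lu <= 1))
  expect_gte(length(unique(w1$current$continent[land])), 2)
})

test_that("continent labels partition land into connected components", {
  w <- test_world()
  cur <- w$current
  land <- cur$land
  expect_true(all(!is.na(cur$continent[land])))
  expect_true(all(is.na(cur$continent[!land])))
  # relabelling by flood fill must reproduce a partition refinement-equal
  # to the stored labels
  relab <- invstack:::label_components(land)
  expect_identical(is.na(relab), is.na(cur$continent))
  tab <- table(relab[land], cur$continent[land])
  expect_true(all(rowSums(tab > 0) == 1)) # each component has one label
})

test_that("predictor-set layer pairs stay within |r| <= 0.70 (oracle check)", {
  for (seed in c(3, 9)) {
    w <- test_world(seed)
    for (ls in w) {
      land_idx <- land_cells(ls)
      for (set in predictor_sets()) {
        vals <- cell_env(ls, set, land_idx)
        for (i in seq_along(set)) {
          for (j in seq_len(i - 1)) {
            r <- cor(vals[[i]], vals[[j]]) # brute-force correlation oracle
            expect_lte(abs(r), 0.70)
          }
        }
      }
    }
  }
})

test_that("scenario warming is ordered: severe > mild > current", {
  w <- test_world()
  land <- w$current$land
  cur_t <- w$current$layers$temp_mean[land]
  mild_t <- w$mild_r1$layers$temp_mean[land]
  sev_t <- w$severe_r1$layers$temp_mean[land]
  expect_gt(mean(mild_t - cur_t), 0)
  expect_gt(mean(sev_t - mild_t), 0)
  # per-cell shifts stay within the smooth-noise amplitude of the target
  sp <- default_scenario_params()
  expect_true(all(abs((mild_t - cur_t) - sp$delta_mild) < 6 * sp$noise_sd))
  expect_true(all(abs((sev_t - cur_t) - sp$delta_severe) < 6 * sp$noise_sd))
})

test_that("degenerate world requests error", {
  expect_error(make_world(1, c(10, 10)), "20")
  bad <- default_scenario_params()
  bad$delta_mild <- 5
  expect_error(make_world(1, c(30, 30), bad), "delta_mild")
})

test_that("effort field is normalized, positive, and centre-proportional", {
  cur <- test_world()$current
  eff1 <- make_effort(1, cur, list(c(10, 10)))
  expect_equal(sum(eff1$effort[cur$land]), 1, tolerance = 1e-9)
  expect_true(all(eff1$effort[cur$land] > 0))
  # single centre on land: maximal effort at that cell
  expect_equal(which.max(eff1$effort), cell_index(cur, 10, 10))
  # duplicated centre: field algebra says the normalized field is unchanged
  eff2 <- make_effort(1, cur, list(c(10, 10), c(10, 10)))
  expect_equal(eff2$effort, eff1$effort, tolerance = 1e-12)
  expect_error(make_effort(1, cur, list()), "centre")
  expect_error(make_effort(1, cur, list(c(1, 1) * NA)), "land")
})

test_that("virtual species niches obey the product-Gaussian invariant", {
  cur <- test_world()$current
  spp <- test_species(3, cur)
  expect_identical(vapply(spp, `[[`, character(1), "id"),
                   c("vs0001", "vs0002", "vs0003"))
  for (sp in spp) {
    s <- sp$suitability[cur$land]
    expect_equal(max(s), 1)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(sp$niche$sigma > 0))
    expect_gte(length(sp$continents), 1)
  }
  # closed-form recomputation at an arbitrary cell
  sp <- spp[[1]]
  cell <- land_cells(cur)[17]
  env <- cell_env(cur, sp$niche$variable, cell)
  g <- prod(exp(-(as.numeric(env) - sp$niche$mu)^2 / (2 * sp$niche$sigma^2)))
  # rescale by the same max used internally
  raw <- rep(1, sum(cur$land))
  env_all <- cell_env(cur, sp$niche$variable)
  for (v in seq_len(nrow(sp$niche))) {
    raw <- raw * exp(-(env_all[[v]] - sp$niche$mu[v])^2 /
                       (2 * sp$niche$sigma[v]^2))
  }
  expect_equal(sp$suitability[cell], g / max(raw), tolerance = 1e-12)

  # very wide niche: suitability approx 1 everywhere on land
  wide <- make_species(1, cur, 1, utils::modifyList(
    default_niche_config(), list(sigma_sd_range = c(500, 600))
  ))[[1]]
  expect_gt(min(wide$suitability[cur$land]), 0.99)

  expect_error(
    make_species(1, cur, 1, utils::modifyList(default_niche_config(),
                                              list(variables = c("x", "y")))),
    "not a landscape layer"
  )
})

test_that("occurrence sampling follows suitability x effort", {
  cur <- test_world()$current
  eff <- test_effort(cur)
  sp <- test_species(1, cur)[[1]]
  o1 <- sample_occurrences(5, sp, eff, cur)
  o2 <- sample_occurrences(5, sp, eff, cur)
  expect_identical(o1$records, o2$records) # seeded determinism
  expect_equal(o1$stage, "raw")
  expect_true(all(cur$land[cell_index(cur, o1$records$row, o1$records$col)]))

  # indicator suitability: all records land in the single suitable cell
  spot <- sp
  spot$error_rate <- 0
  spot$suitability[] <- NA_real_
  spot$suitability[cur$land] <- 0
  target <- land_cells(cur)[42]
  spot$suitability[target] <- 1
  ost <- sample_occurrences(5, spot, eff, cur)
  expect_true(all(cell_index(cur, ost$records$row, ost$records$col) == target))

  # two-cell weight ratio 3:1 converges to a 3:1 record split
  duo <- spot
  duo$lambda <- 20000
  a <- land_cells(cur)[10]
  b <- land_cells(cur)[100]
  duo$suitability[cur$land] <- 0
  duo$suitability[a] <- 3 / eff$effort[a]
  duo$suitability[b] <- 1 / eff$effort[b]
  od <- sample_occurrences(5, duo, eff, cur)
  n <- nrow(od$records)
  na <- sum(cell_index(cur, od$records$row, od$records$col) == a)
  p_hat <- na / n
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(p_hat - 0.75), 3 * se)

  zero <- spot
  zero$suitability[cur$land] <- 0
  expect_error(sample_occurrences(5, zero, eff, cur), "identically zero")
})

test_that("large-sample occurrence frequencies match the sampling law", {
  cur <- test_world()$current
  eff <- test_effort(cur)
  sp <- test_species(1, cur)[[1]]
  sp$error_rate <- 0
  sp$lambda <- 1e5
  occ <- sample_occurrences(9, sp, eff, cur)
  cells <- cell_index(cur, occ$records$row, occ$records$col)
  land_idx <- land_cells(cur)
  w <- sp$suitability[land_idx] * eff$effort[land_idx]
  p <- w / sum(w)
  obs <- tabulate(match(cells, land_idx), nbins = length(land_idx))
  keep <- p * length(cells) >= 5 # chi-square validity
  chi <- sum((obs[keep] - length(cells) * p[keep])^2 /
               (length(cells) * p[keep]))
  pval <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})
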