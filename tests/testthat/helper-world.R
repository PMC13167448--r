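# shared small fixtures, built once per test run

.fixtures <- new.env()

test_world <- function(seed = 3, shape = c(40, 40)) {
  key <- paste0("w", seed, "_", shape[1], "x", shape[2])
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_world(seed, shape)
  }
  .fixtures[[key]]
}

test_effort <- function(ls = test_world()$current) {
  key <- paste0("eff_", ls$seed, "_", ls$nrows)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_effort(1, ls, list(c(10, 10), c(30, 30)))
  }
  .fixtures[[key]]
}

test_species <- function(n = 3, ls = test_world()$current) {
  key <- paste0("spp_", ls$seed, "_", n)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_species(3, ls, n)
  }
  .fixtures[[key]]
}

# one fully prepared species (presences, PAs, blocks) on the 40x40 world;
# among the candidate species the one with the most even spread of
# presences over the spatial blocks is used, so the fixture is a
# "strong-signal, well-sampled" instance rather than a degenerate one
test_calibration <- function() {
  if (is.null(.fixtures$calib)) {
    w <- test_world()
    cur <- w$current
    eff <- test_effort(cur)
    best <- NULL
    for (sp in test_species(6, cur)) {
      occ <- sample_occurrences(3, sp, eff, cur)
      prep <- prepare_occurrences(
        occ, unique(c(climatic_vars("set1"), climatic_vars("set2"))), seed = 3
      )
      if (!prep$accepted) next
      pres <- prep$occ
      cells <- cell_index(cur, pres$records$row, pres$records$col)
      sre <- fit_sre(pres$records[climatic_vars("set1")])
      pa <- try(sample_pa(sre, cur, eff, nrow(pres$records), cells,
                          seed = 3, species_id = sp$id), silent = TRUE)
      if (inherits(pa, "try-error")) next
      blocks <- try(make_blocks(rbind(pres$records[c("row", "col")],
                                      pa$records[c("row", "col")])),
                    silent = TRUE)
      if (inherits(blocks, "try-error")) next
      spread <- min(table(factor(blocks[seq_len(nrow(pres$records))],
                                 levels = 1:4)))
      cand <- list(world = w, cur = cur, effort = eff, species = sp,
                   raw = occ, pres = pres, cells = cells, sre = sre,
                   pa = pa, blocks = blocks, spread = spread)
      if (is.null(best) || spread > best$spread) best <- cand
    }
    .fixtures$calib <- best
  }
  .fixtures$calib
}

# a tiny landscape with hand-set layers for exact-value tests
toy_landscape <- function(nr = 6, nc = 6) {
  layers <- lapply(seq_along(invstack:::LAYER_NAMES), function(i) {
    matrix(seq(0, 1, length.out = nr * nc) + i, nr, nc)
  })
  names(layers) <- invstack:::LAYER_NAMES
  land <- matrix(TRUE, nr, nc)
  land[1, 1] <- FALSE
  continent <- matrix(1L, nr, nc)
  continent[, seq_len(floor(nc / 2))] <- 2L
  continent[!land] <- NA_integer_
  invstack:::new_landscape(nr, nc, layers, land, continent, "current", 1L)
}
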