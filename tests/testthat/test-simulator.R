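test_that("initial conditions follow the stated distributions", {
  set.seed(15)
  cells <- replicate(20000, {
    c0 <- sampleInitialConditions()
    c(length(c0$site_status), c0$synapse_fraction, c0$free_monomers,
      length(c0$auto_state))
  })
  ## gamma site counts: mean within 3 SE of shape * scale
  m <- 1.59 * 15.92
  se <- sqrt(1.59) * 15.92 / sqrt(ncol(cells))
  expect_lt(abs(mean(cells[1, ]) - m), 3 * se + 0.5)  # +0.5 for rounding
  ## synapse fraction
  expect_lt(abs(mean(cells[2, ]) - 0.40), 3 * 0.025 / sqrt(ncol(cells)))
  ## monomers: mean within 3 SE of 108000
  expect_lt(abs(mean(cells[3, ]) - 108000), 3 * 3600 / sqrt(ncol(cells)) + 1)
  ## autophagosomes: gamma(4.30, 7.90)
  ma <- 4.30 * 7.90
  sea <- sqrt(4.30) * 7.90 / sqrt(ncol(cells))
  expect_lt(abs(mean(cells[4, ]) - ma), 3 * sea + 0.5)
  ## truncation: nothing negative
  expect_true(all(cells >= 0))

  set.seed(99); a <- sampleInitialConditions()
  set.seed(99); b <- sampleInitialConditions()
  expect_identical(a, b)
})

test_that("growth pmf matches the closed forms and normalizes", {
  ## pre-barrier lengths are binomial
  expect_equal(growthPmf(10, 3, 50, 0.3, 0.8), dbinom(3, 10, 0.3),
               tolerance = 1e-12)
  expect_equal(round(growthPmf(10, 3, 50, 0.3, 0.8), 4), 0.2668)
  ## impossible lengths
  expect_equal(growthPmf(10, 11, 5, 0.3, 0.8), 0)
  ## normalization in log space up to n = 200
  for (n in c(20, 120, 200))
    expect_lt(abs(sum(growthPmf(n, 0:n, 5, 0.3, 0.8)) - 1), 1e-9)
  expect_error(growthPmf(10, 2, 5, 1.3, 0.5))
})

test_that("growth pmf equals a brute-force two-phase Bernoulli simulation", {
  set.seed(24)
  n <- 20; L0 <- 5; pa <- 0.3; pg <- 0.8; reps <- 2e5
  len <- integer(reps)
  for (i in seq_len(n)) {
    p <- ifelse(len < L0, pa, pg)
    len <- len + (runif(reps) < p)
  }
  emp <- tabulate(len + 1L, n + 1) / reps
  thr <- growthPmf(n, 0:n, L0, pa, pg)
  se <- sqrt(thr * (1 - thr) / reps)
  expect_true(all(abs(emp - thr) <= 3 * pmax(se, 1e-9) + 1e-8))
})

test_that("degenerate parameter settings freeze the expected dynamics", {
  set.seed(41)
  ## no activation: the monomer pool never moves and no filament appears
  cell <- newSimCell(20, 0.4, 5000, 0)
  res <- runCell(cell, SimParams(pActivate = 0, maxIter = 200), mode = "growth")
  expect_equal(res$state$free_monomers, 5000)
  expect_length(res$lengths, 0)
  expect_equal(res$iterations, 200)
  expect_equal(nrow(res$trace), 201)          # max_iter + 1 trace rows

  ## no degradation: filaments never shorten, no scission
  cell <- newSimCell(10, 0.4, 2000, 15)
  p0 <- SimParams(pActivate = 0.5, pAttach = 0.1, pDegrade = 0, maxIter = 300)
  prev <- -1
  st <- cell
  for (k in 1:5) {
    st <- stepCell(st, p0)
    tot <- sum(st$fil_len[st$fil_len > 0])
    expect_gte(tot, prev)
    prev <- tot
  }
  res <- runCell(cell, p0)
  expect_equal(res$state$degraded_monomers, 0)
  expect_true(all(res$state$fil_site[res$state$fil_len > 0] >= 0)) # no daughters
})

test_that("the integer monomer ledger balances at every iteration", {
  set.seed(42)
  for (cfg in list(list(pd = 0, mode = "growth"),
                   list(pd = 0.3, mode = "growth+degradation"))) {
    cell <- newSimCell(15, 0.4, 20000, 12)
    res <- runCell(cell, SimParams(pActivate = 0.5, pAttach = 0.1,
                                   pDegrade = cfg$pd, maxIter = 2000),
                   mode = cfg$mode)
    tr <- res$trace
    expect_true(all(tr[, "free"] + tr[, "filamentous"] + tr[, "degraded"] ==
                      20000))
  }
})

test_that("growth-only runs terminate exactly at monomer depletion", {
  set.seed(43)
  cell <- newSimCell(25, 0.4, 8000, 0)
  res <- runCell(cell, SimParams(pActivate = 0.5, pAttach = 0.1), "growth")
  expect_equal(res$state$free_monomers, 0)
  expect_equal(sum(res$lengths), 8000)

  ## forced decay: everything degrades before the cap
  cell <- newSimCell(6, 0.4, 400, 40)
  res <- runCell(cell, SimParams(pActivate = 0.8, pAttach = 0.5, pDegrade = 1,
                                 pCollideAuto = 1, pAttachAuto = 1,
                                 maxIter = 10000), "growth+degradation")
  expect_equal(res$state$free_monomers + sum(pmax(res$state$fil_len, 0)), 0)
  expect_lt(res$iterations, 10000)
  expect_equal(res$state$degraded_monomers, 400)
})

test_that("population runs expose the negative puncta-length correlation", {
  set.seed(44)
  cells <- replicate(40, sampleInitialConditions(withAutophagosomes = FALSE),
                     simplify = FALSE)
  pop <- runPopulation(cells, SimParams(pActivate = 0.5, pAttach = 0.1),
                       n_trials = 3, mode = "growth")
  expect_lt(pop$rho, 0)
  expect_true(all(vapply(seq_along(cells), function(i)
    sum(pop$lengths[[i]]) == 3 * cells[[i]]$free_monomers, TRUE)))

  ## identical cells with zero puncta variance give the undefined sentinel
  same <- replicate(5, newSimCell(0, 0.4, 100, 0), simplify = FALSE)
  pop0 <- runPopulation(same, SimParams(pActivate = 0), n_trials = 1,
                        mode = "growth")
  expect_true(is.na(pop0$rho))
})

test_that("raising degradation lowers peak filamentous concentration and n_half follows n_max", {
  set.seed(45)
  cells <- replicate(12, {
    c0 <- sampleInitialConditions()
    newSimCell(length(c0$site_status), c0$synapse_fraction, 20000,
               length(c0$auto_state))
  }, simplify = FALSE)
  peaks <- c()
  for (pd in c(0.05, 0.3)) {
    set.seed(46)
    pop <- runPopulation(cells, SimParams(pActivate = 0.5, pAttach = 0.1,
                                          pDegrade = pd, maxIter = 2500),
                         n_trials = 2, mode = "growth+degradation",
                         record_curves = TRUE)
    ## curves rise to a maximum then decay
    mc <- pop$concentration
    expect_equal(max(mc), 1)
    expect_lt(mc[length(mc)], 1)
    peaks <- c(peaks, pop$peak)
    ok <- is.finite(pop$n_half)
    expect_true(all(pop$n_half[ok] > pop$n_max[ok]))
  }
  expect_lte(peaks[2], peaks[1])
})
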