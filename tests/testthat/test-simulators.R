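test_that("Moore neighborhoods have the right size and wrap correctly", {
  expect_length(neighbor_indices(10, 10, 20, 20, "truncated"), 8)
  expect_length(neighbor_indices(1, 1, 20, 20, "truncated"), 3)
  expect_length(neighbor_indices(1, 10, 20, 20, "truncated"), 5)
  # torus: all eight wrapped offsets are distinct cells on a 3x3 lattice
  nb <- neighbor_indices(1, 1, 3, 3, "torus")
  expect_length(nb, 8)
  expect_length(unique(nb), 8)
  expect_false(1 %in% nb) # never the focal cell (index of (1,1) is 1)
  expect_error(neighbor_indices(0, 1, 3, 3), "outside")
  expect_error(neighbor_indices(1, 4, 3, 3), "outside")
})

test_that("zero-sum dynamics conserve plot size at every snapshot", {
  meta <- tiny_meta()
  set.seed(101)
  cfg <- implicit_config(6, 80, 0.3, 40)
  state <- NULL
  for (chunk in 1:4) {
    cfg$generations <- 10
    mat <- run_implicit(meta, cfg, init = state, keep_state = TRUE)
    state <- attr(mat, "state")
    expect_true(all(rowSums(mat) == 80))
  }
  lat <- run_lattice(meta, lattice_config(4, 4, 50, 0.1, 0.1, 30))
  expect_true(all(rowSums(lat) == 50))
})

test_that("pure metacommunity recruitment reproduces direct samples", {
  meta <- tiny_meta()
  set.seed(102)
  mat <- run_implicit(meta, implicit_config(30, 100, 1, 10))
  sim_S <- apply(mat, 1, function(r) sum(r > 0))
  direct_S <- replicate(200, sum(sample_community(meta, 100) > 0))
  se <- sqrt(stats::var(direct_S) / length(sim_S) +
             stats::var(direct_S) / length(direct_S))
  expect_lt(abs(mean(sim_S) - mean(direct_S)), 4 * se)
})

test_that("pure drift fixes every plot on a single species", {
  meta <- tiny_meta()
  set.seed(103)
  mat <- run_implicit(meta, implicit_config(12, 20, 0, 100))
  expect_true(all(apply(mat, 1, function(r) sum(r > 0)) == 1))
})

test_that("J = 2 implicit chain matches exact Moran enumeration", {
  meta <- two_species_meta()
  # mixed plots; one event per plot (= 0.5 generations at J = 2)
  n_plots <- 3000
  init <- matrix(rep(c(1L, 2L), n_plots), nrow = 2)
  # m = 0: the recruit always copies the survivor, fixing the plot
  set.seed(104)
  cfg <- implicit_config(n_plots, 2, 0, 0.5)
  mat <- run_implicit(meta, cfg, init = init)
  expect_true(all(apply(mat, 1, max) == 2))
  # m = 0.4: P(stay mixed) = m * 1/2 exactly (dead species redrawn from pool)
  cfg$m <- 0.4
  mat <- run_implicit(meta, cfg, init = init)
  mixed <- mean(apply(mat, 1, function(r) all(r == 1)))
  p <- 0.4 / 2
  expect_lt(abs(mixed - p), 3 * sqrt(p * (1 - p) / n_plots))
})

test_that("lattice sweep with forced adjacent recruitment matches the
           hand-enumerated two-plot chain", {
  meta <- two_species_meta()
  # plots (A,B) and (A,A); m_adj = 1; one sweep (plot 1 then plot 2):
  # end states (AA,AA) w.p. 1/2, (AB,AA) w.p. 1/4, (AB,AB) w.p. 1/4
  cfg <- lattice_config(2, 1, 2, 1, 0, 0.5)
  init <- matrix(c(1L, 2L, 1L, 1L), nrow = 2)
  set.seed(105)
  n <- 4000
  states <- replicate(n, {
    mat <- run_lattice(meta, cfg, init = init)
    paste0(ifelse(apply(mat, 1, max) == 2, "F", "M"), collapse = "")
  })
  freq <- table(factor(states, levels = c("FF", "MF", "MM")))
  probs <- c(FF = 0.5, MF = 0.25, MM = 0.25)
  for (s in names(probs))
    expect_lt(abs(freq[[s]] / n - probs[[s]]),
              3 * sqrt(probs[[s]] * (1 - probs[[s]]) / n))
})

test_that("recruitment source frequencies follow the configured PMF", {
  meta <- tiny_meta()
  set.seed(106)
  lat <- run_lattice(meta, lattice_config(5, 5, 100, 0.3, 0.2, 60))
  src <- attr(lat, "sources")
  tot <- sum(src)
  expect_gte(tot, 1e5)
  pmf <- c(local = 0.5, adjacent = 0.3, meta = 0.2)
  for (nm in names(pmf))
    expect_lt(abs(src[[nm]] / tot - pmf[[nm]]),
              3 * sqrt(pmf[[nm]] * (1 - pmf[[nm]]) / tot))
})

test_that("lattice with m_adj = 0 reproduces the implicit model", {
  meta <- tiny_meta()
  set.seed(107)
  n_rep <- 4
  stat <- function(mat) c(S = sum(colSums(mat) > 0),
                          Fw = mean(apply(mat, 1, simpson_identity)))
  imp <- replicate(n_rep, stat(run_implicit(meta, implicit_config(16, 100, 0.2, 60))))
  lat <- replicate(n_rep, stat(run_lattice(meta, lattice_config(4, 4, 100, 0, 0.2, 60))))
  for (k in 1:2) {
    se <- sqrt(stats::var(imp[k, ]) / n_rep + stats::var(lat[k, ]) / n_rep)
    expect_lt(abs(mean(imp[k, ]) - mean(lat[k, ])), 4 * se + 1e-9)
  }
})

test_that("stationarity traces behave as theory predicts at the extremes", {
  meta <- tiny_meta()
  set.seed(108)
  # m = 1: richness flat from generation 0 within sampling noise
  tr1 <- stationarity_trace(meta, implicit_config(10, 100, 1, 40), 10)
  expect_lt(diff(range(tr1$richness)), 0.25 * mean(tr1$richness))
  # m = 0: mean within-plot identity rises toward 1
  tr0 <- stationarity_trace(meta, implicit_config(10, 100, 0, 80), 20)
  expect_gt(tail(tr0$mean_identity, 1), tr0$mean_identity[1])
  expect_gt(tail(tr0$mean_identity, 1), 0.9)
  # moderate m: identity plateau matches the moment relation
  # E[F] = (I*F_meta + 1)/(I + 1), I = m(J-1)/(1-m)
  set.seed(109)
  J <- 500; m <- 0.2
  tr <- stationarity_trace(meta, implicit_config(20, J, m, 60), 20)
  I <- m * (J - 1) / (1 - m)
  Fmeta <- simpson_identity(round(meta$abundance))
  expect_equal(tail(tr$mean_identity, 1), (I * Fmeta + 1) / (I + 1),
               tolerance = 0.12)
})

test_that("lattice config validates the recruitment PMF", {
  expect_error(lattice_config(4, 4, 50, 0.7, 0.6), "exceed 1")
})
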