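test_that("simpson identity equals the pairwise enumeration", {
  expect_equal(simpson_identity(5), 1)
  expect_equal(simpson_identity(c(1, 1)), 0)
  expect_equal(simpson_identity(c(2, 2)), 1 / 3) # 2 conspecific of 6 pairs
  expect_error(simpson_identity(1), "at least 2")
})

test_that("Dirichlet-multinomial likelihood normalizes and hits its limits", {
  # single draw: probability is p_i
  expect_equal(dm_loglik(c(1, 0), 2.5, c(0.3, 0.7)), log(0.3))
  # normalization over all compositions of J for several (I, p)
  for (I in c(0.7, 1, 10)) {
    for (p in list(c(0.5, 0.5), c(0.2, 0.8), c(0.1, 0.3, 0.6))) {
      comps <- all_compositions(3, length(p))
      tot <- sum(vapply(comps, function(n) exp(dm_loglik(n, I, p)), 1))
      expect_lt(abs(tot - 1), 1e-9)
    }
  }
  # I -> Inf: multinomial limit
  n <- c(4, 2, 1)
  p <- c(0.5, 0.3, 0.2)
  expect_equal(dm_loglik(n, 1e9, p),
               stats::dmultinom(n, prob = p, log = TRUE), tolerance = 1e-6)
  # unobservable species
  expect_identical(dm_loglik(c(1, 1), 1, c(1, 0)), -Inf)
})

test_that("Etienne sampling formula normalizes over partitions", {
  expect_equal(as.numeric(etienne_loglik(1, 2, 3)), 0) # J = 1: probability 1
  for (ti in list(c(2, 3), c(0.5, 1), c(8, 0.3))) {
    tot <- sum(vapply(all_partitions(5),
                      function(n) exp(as.numeric(etienne_loglik(n, ti[1], ti[2]))), 1))
    expect_lt(abs(tot - 1), 1e-9)
  }
  tot6 <- sum(vapply(all_partitions(6),
                     function(n) exp(as.numeric(etienne_loglik(n, 1.5, 2))), 1))
  expect_lt(abs(tot6 - 1), 1e-9)
})

test_that("Etienne formula converges to the Ewens sampling formula", {
  for (n in all_partitions(6)) {
    et <- exp(as.numeric(etienne_loglik(n, 1.5, 1e8)))
    ew <- exp(ewens_loglik(n, 1.5))
    expect_lt(abs(et - ew) / ew, 1e-6)
  }
  # Ewens itself normalizes
  tot <- sum(vapply(all_partitions(6), function(n) exp(ewens_loglik(n, 1.5)), 1))
  expect_lt(abs(tot - 1), 1e-9)
})

test_that("ewens_theta inverts the expected-species relation", {
  expect_equal(ewens_theta(1, 50), 0)
  expect_warning(th <- ewens_theta(5, 5), "unbounded")
  expect_identical(th, Inf)
  # forward check at a solved value
  th <- ewens_theta(40, 1000)
  expect_lt(abs(th * (digamma(th + 1000) - digamma(th)) - 40) / 40, 1e-8)
  # recovery from simulated Ewens samples (CRP oracle)
  set.seed(201)
  th_hat <- replicate(200, ewens_theta(length(crp_sample(3, 100)), 100))
  expect_equal(mean(th_hat), 3, tolerance = 0.15)
})

test_that("Gst estimator recovers the implicit-model migration", {
  set.seed(202)
  mat <- run_implicit(mc_low(), implicit_config(50, 625, 0.3, 200))
  g <- gst_migration(mat)
  expect_lt(abs(g$mean - 0.3), 0.03)
  expect_true(all(g$m_hat >= 0 & g$m_hat <= 1))
  expect_equal(g$mean, mean(g$m_hat))
})

test_that("undifferentiated plots are capped at m = 1 and flagged", {
  row <- c(30, 20, 10, 5)
  mat <- rbind(row, row, row)
  g <- gst_migration(mat)
  expect_true(all(g$m_hat == 1))
  expect_true(all(g$flags == "undifferentiated"))
  expect_error(gst_migration(mat[1, , drop = FALSE]), "at least 2 plots")
})

test_that("Inference estimator recovers the implicit-model migration", {
  set.seed(203)
  mat <- run_implicit(mc_low(), implicit_config(50, 625, 0.1, 200))
  i <- inference_migration(mat)
  expect_lt(abs(i$mean - 0.1), 0.02)
  # copies of the pooled proportions push the fit to the upper cap
  row <- c(300, 200, 100, 25)
  mat2 <- rbind(row, row, row)
  i2 <- inference_migration(mat2)
  expect_true(all(i2$flags == "upper-bound"))
  expect_true(all(i2$m_hat > 0.99))
})

test_that("one-stage fit recovers theta from an Ewens sample", {
  set.seed(204)
  fit <- etienne_onestage(crp_sample(5, 100))
  expect_gt(fit$theta_hat, 2)
  expect_lt(fit$theta_hat, 12)
  expect_gt(fit$m_hat, 0.5) # no dispersal limitation in the generating model
  # monoculture: m at the zero boundary, flagged
  mono <- etienne_onestage(c(50))
  expect_equal(mono$m_hat, 0)
  expect_equal(mono$flag, "boundary")
})

test_that("two-stage fit recovers migration with theta from the pool", {
  set.seed(205)
  mat <- run_implicit(mc_low(), implicit_config(20, 100, 0.25, 200))
  ts <- twostage_migration(mat)
  expect_lt(abs(ts$mean - 0.25), 0.06)
  expect_true(all(is.finite(ts$theta_hat)))
  # plots that are direct metacommunity samples sit near the m = 1 cap
  set.seed(215)
  mat1 <- run_implicit(mc_spatial(), implicit_config(5, 100, 1, 20))
  ts1 <- twostage_migration(mat1)
  expect_gt(ts1$mean, 0.85)
  expect_true(all(ts1$m_hat > 0.6))
})

test_that("singleton ratio diagnoses mixing", {
  # hand-built pooled sample: counts (8,1,1), two observed singletons
  mat <- matrix(c(8, 1, 1), nrow = 1)
  a <- fishers_alpha(10, 3)
  expect_equal(singleton_ratio(mat), 2 / expected_singletons(10, a))
  # a fresh logseries draw is well mixed: ratio near 1
  set.seed(206)
  draw <- matrix(sample_community(mc_spatial(), 2e5), nrow = 1)
  expect_gt(singleton_ratio(draw), 0.75)
  expect_lt(singleton_ratio(draw), 1.25)
  # a low-migration simulation has fewer singletons than the logseries expects
  mat_lo <- run_implicit(mc_low(), implicit_config(20, 625, 0.05, 200))
  expect_lt(singleton_ratio(mat_lo), 1)
})
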