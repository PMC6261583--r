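# Least-squares fitting of the bilinear compartment model.

# conservative meeting-driven conversion on two traits (logistic invasion)
logistic_rates <- function(mu = 2e-3) {
  A <- matrix(0, 5, 2, dimnames = list(NULL, c("res", "inv")))
  A[4, 1] <- -mu   # res loses on res*inv meetings
  A[4, 2] <- mu    # inv gains
  A
}

test_that("derivative estimates are exact on constants and lines", {
  s <- cbind(a = rep(0.4, 50), b = rep(0.6, 50))
  expect_true(all(estimate_derivatives(s) == 0))
  t <- 0:49
  lin <- cbind(a = 0.1 + 0.002 * t, b = 0.9 - 0.002 * t)
  d <- estimate_derivatives(lin)
  expect_equal(unname(d[, 1]), rep(0.002, 50), tolerance = 1e-12)
  expect_equal(unname(d[, 2]), rep(-0.002, 50), tolerance = 1e-12)
  expect_error(estimate_derivatives(lin[1:2, ]), "at least 3")
})

test_that("central differences track a sine ramp within O(h^2)", {
  t <- 0:400
  w <- 0.2
  s <- cbind(x = 0.5 + 0.3 * sin(w * t))
  d <- estimate_derivatives(s)
  truth <- 0.3 * w * cos(w * t)
  interior <- 2:400
  expect_lt(max(abs(d[interior, 1] - truth[interior])), 0.3 * w^3 / 6 + 1e-12)
})

test_that("the design matrix has m + m(m+1)/2 ordered columns", {
  s2 <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  F2 <- build_design(s2)
  expect_equal(ncol(F2), 5)
  expect_identical(colnames(F2), c("a", "b", "a*a", "a*b", "b*b"))
  expect_equal(F2[, "a*b"], s2[, 1] * s2[, 2])
  s6 <- matrix(runif(60), 10, 6)
  expect_equal(ncol(build_design(s6)), 27)
  # an extinct trait zeroes its linear and product columns
  s2[, 2] <- 0
  F0 <- build_design(s2)
  expect_true(all(F0[, c("b", "a*b", "b*b")] == 0))
})

test_that("fit_rates equals the brute-force normal-equations oracle", {
  set.seed(20)
  F <- matrix(rnorm(240), 40, 6)
  sdot <- matrix(rnorm(80), 40, 2)
  A <- fit_rates(F, sdot)$A
  oracle <- solve(t(F) %*% F, t(F) %*% sdot)
  expect_lt(max(abs(A - oracle)), 1e-10)
  # residuals orthogonal to the design columns
  expect_lt(max(abs(t(F) %*% (sdot - F %*% A))), 1e-8)
  # exact representation: sdot = first design column
  A1 <- fit_rates(F, F[, 1, drop = FALSE])$A
  expect_equal(unname(A1[, 1]), c(1, 0, 0, 0, 0, 0), tolerance = 1e-10)
})

test_that("noise-free recovery of identifiable rate sets is exact", {
  # off-simplex trajectories (net decay) keep the design full rank
  A_true <- matrix(c(-3e-3, 5e-4, 1e-4, -2e-4, 1e-4,
                     4e-4, -2e-3, 0, 1e-4, -1e-4), 5, 2)
  s0 <- c(0.6, 0.4)
  s <- generate_synthetic_series(A_true, s0, 400)
  keep <- 1:400   # the final forward difference is padded, not observed
  sdot <- estimate_derivatives(s, method = "forward")[keep, ]
  F <- build_design(s)[keep, ]
  fit <- fit_rates(F, sdot)
  expect_equal(fit$rank, 5)
  expect_lt(max(abs(fit$A - A_true)) / max(abs(A_true)), 1e-6)
})

test_that("conservative systems fit via minimum norm and conserve mass", {
  A_true <- logistic_rates()
  s <- generate_synthetic_series(A_true, c(0.95, 0.05), 1500)
  keep <- 1:1500
  # on-simplex fractions make the design structurally rank deficient
  sdot <- estimate_derivatives(s, method = "forward")[keep, ]
  F <- build_design(s)[keep, ]
  expect_warning(fit <- fit_rates(F, sdot), "rank deficient")
  # predictions are exact even though A itself is only identifiable up to
  # the null space of F
  rep <- reconstruct_and_check(F, fit, s[1, ], sdot)
  expect_lt(max(abs(rep$E - sdot)), 1e-10)
  expect_lt(max(abs(rep$reconstructed - s[keep, ])), 1e-8)
  expect_gte(rep$conservation_decimal_places, 4)
  expect_lt(rep$max_normal_eq_residual, 1e-8)
})

test_that("predicted derivatives of on-simplex series sum to zero", {
  set.seed(21)
  ts <- run_simulation(sim_config(ticks = 1200, seed = 31, cost = 0.2,
                                  allowed_deceptions = c("None", "Corruption")))
  s <- trait_fractions(ts, "six")
  sdot <- estimate_derivatives(s)
  F <- build_design(s)
  fit <- suppressWarnings(fit_rates(F, sdot))
  E <- F %*% fit$A
  expect_lt(max(abs(rowSums(E))), 1e-10)
  rep <- reconstruct_and_check(F, fit, s[1, ])
  expect_gte(rep$conservation_decimal_places, 4)
})

test_that("zero rates reconstruct a constant series", {
  s0 <- c(0.3, 0.7)
  A0 <- matrix(0, 5, 2)
  s <- generate_synthetic_series(A0, s0, 50)
  expect_true(all(s[, 1] == 0.3 & s[, 2] == 0.7))
  F <- build_design(s)
  rep <- reconstruct_and_check(F, A0, s0)
  expect_true(all(rep$E == 0))
  expect_true(all(rep$reconstructed[, 1] == 0.3))
  expect_equal(rep$conservation_decimal_places, Inf)
})

test_that("meeting-driven conversion produces an S-shaped invasion", {
  s <- generate_synthetic_series(logistic_rates(3e-3), c(0.95, 0.05), 3000)
  inv <- s[, "inv"]
  expect_true(all(diff(inv) > -1e-12))      # monotone growth
  expect_gt(max(inv), 0.9)                  # saturates near fixation
  # inflection: growth accelerates then decelerates
  expect_gt(which.max(diff(inv)), 100)
  expect_lt(which.max(diff(inv)), 2900)
  # mass conserved by the conservative rate set
  expect_lt(max(abs(rowSums(s) - 1)), 1e-9)
})

test_that("trajectories leaving [0, 1] error with the offending tick", {
  A_bad <- matrix(0, 5, 2)
  A_bad[1, 1] <- 0.5   # explosive spontaneous growth
  expect_error(generate_synthetic_series(A_bad, c(0.9, 0.1), 50),
               "leaves \\[0, 1\\] at tick")
  expect_error(generate_synthetic_series(A_bad, c(0.5, 0.4), 50), "sum to 1")
})

test_that("fit_decay recovers exponential rates", {
  t <- 0:300
  s <- 0.5 * exp(-0.01 * t)
  expect_equal(fit_decay(s), 0.01, tolerance = 1e-9)
  expect_equal(fit_decay(rep(0.4, 100)), 0)
  expect_error(fit_decay(c(0.1, 0, 0.1)), "strictly positive")
  # windowed fit on a partial trace
  expect_equal(fit_decay(s, window = 50:200), 0.01, tolerance = 1e-9)
  # noisy Monte-Carlo recovery
  set.seed(22)
  rates <- replicate(30, fit_decay(s * (1 + rnorm(length(s), 0, 0.01))))
  expect_equal(mean(rates), 0.01, tolerance = 0.002)
  expect_true(all(abs(rates - 0.01) < 0.002))
})

test_that("noisy observations still recover the dynamics within 10%", {
  A_true <- logistic_rates(0.01)
  set.seed(23)
  s <- generate_synthetic_series(A_true, c(0.95, 0.05), 2000,
                                 noise_sd = 0.005)
  fit <- suppressWarnings(fit_rates(build_design(s),
                                    estimate_derivatives(s)))
  # evaluate the recovered and generating rate fields on the clean states
  clean <- generate_synthetic_series(A_true, c(0.95, 0.05), 2000)
  pred_true <- build_design(clean) %*% A_true
  pred_fit <- build_design(clean) %*% fit$A
  expect_lt(sqrt(mean((pred_fit - pred_true)^2)) /
              sqrt(mean(pred_true^2)), 0.1)
})
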