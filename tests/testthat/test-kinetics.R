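test_that("TST prefactor and published-row recomputation agree", {
  # zero barrier, no tunneling: the universal frequency factor kB*T/h
  expect_equal(tst_rate(0), 6.212e12, tolerance = 1e-3)
  # printed barriers carry 0.1 kcal/mol rounding, hence the 10% band
  expect_equal(tst_rate(16.7, kappa = 195.2), 7.29e2, tolerance = 0.10)
  expect_equal(tst_rate(14.5, kappa = 428.7), 6.43e4, tolerance = 0.10)
  # strictly decreasing and log-linear in the barrier
  dg <- seq(2, 30, by = 0.5)
  lk <- log10(tst_rate(dg))
  slopes <- diff(lk) / diff(dg)
  pc <- phys_constants()
  expect_equal(slopes, rep(-1 / (pc$R_kcal * 298.15 * log(10)),
                           length(slopes)), tolerance = 1e-9)
  expect_warning(tst_rate(-1), "negative")
  expect_error(tst_rate(10, kappa = 0.5))
})

test_that("Wigner kappa has the right value, limits and monotonicity", {
  expect_equal(wigner_kappa(0), 1)
  expect_equal(wigner_kappa(1000, 298.15), 1.9703, tolerance = 1e-4)
  nu <- seq(0, 3000, by = 250)
  expect_true(all(diff(wigner_kappa(nu)) > 0))
  expect_true(all(wigner_kappa(nu, 1000) < wigner_kappa(nu + 1, 298.15)))
})

test_that("Eckart kappa matches a dense-trapezoid oracle to 4 significant figures", {
  cases <- list(c(5, 5, 1500), c(8, 3, 1200), c(4, 12, 2000),
                c(16, 18, 2500), c(2, 2, 800))
  for (cs in cases) {
    k <- eckart_kappa(cs[1], cs[2], cs[3])
    expect_equal(k, eckart_oracle(cs[1], cs[2], cs[3]), tolerance = 5e-5)
  }
})

test_that("Eckart kappa respects the classical and high-temperature limits", {
  expect_equal(eckart_kappa(5, 5, 1e-3), 1, tolerance = 1e-3)
  expect_equal(eckart_kappa(5, 5, 1500, temperature = 5000), 1,
               tolerance = 0.05)
  # kappa >= 1 across randomized barriers and frequencies
  set.seed(20261001)
  for (i in 1:40) {
    vf <- runif(1, 0.5, 25); vr <- runif(1, 0.5, 25)
    nu <- runif(1, 100, 3500)
    expect_gte(eckart_kappa(vf, vr, nu), 1)
  }
  expect_error(eckart_kappa(-1, 5, 1000))
})

test_that("Marcus barrier is a symmetric parabola with the right anchor points", {
  expect_equal(marcus_activation(-5.0, 5.0), 0)          # barrierless point
  expect_equal(marcus_activation(0, 5.0), 1.25)          # lambda/4
  expect_equal(marcus_activation(1.78, 5.0), 2.30, tolerance = 1e-3)
  set.seed(7)
  for (i in 1:25) {
    lambda <- runif(1, 1, 20); x <- runif(1, 0, 30)
    expect_equal(marcus_activation(-lambda + x, lambda),
                 marcus_activation(-lambda - x, lambda), tolerance = 1e-12)
  }
  expect_error(marcus_activation(1, 0), "> 0")
})

test_that("reorganization energy is the vertical/adiabatic SET gap", {
  expect_equal(reorganization_energy(36.4, 31.4), 5.0)
  expect_error(reorganization_energy(5, 5))               # lambda = 0
  expect_equal(reorganization_energy(36.4 + 3, 31.4 + 3), 5.0)
})

test_that("Smoluchowski rate scales as expected and matches its oracle", {
  k1 <- diffusion_rate_constant(3e-10, 3e-10, 8.91e-4)
  expect_equal(k1, 7.419e9, tolerance = 1e-3)             # direct evaluation
  expect_equal(diffusion_rate_constant(3e-10, 3e-10, 2 * 8.91e-4),
               k1 / 2, tolerance = 1e-12)
  # for equal radii the r and 1/r factors cancel: k_D is radius-free
  expect_equal(diffusion_rate_constant(5e-10, 5e-10, 8.91e-4), k1,
               tolerance = 1e-12)
})

test_that("Collins-Kimball apparent rate interpolates between regimes", {
  expect_equal(apparent_rate(2e9, 2e9), 1e9)
  expect_equal(apparent_rate(1e3, 1e10), 1e3, tolerance = 1e-6)
  expect_equal(apparent_rate(1e14, 7.8e9), 7.8e9, tolerance = 1e-4)
  expect_equal(apparent_rate(0, 0), 0)
  expect_equal(apparent_rate(123), 123)                   # gas phase
  set.seed(11)
  ka <- 10^runif(50, -5, 14); kd <- 10^runif(50, 8, 11)
  expect_true(all(apparent_rate(ka, kd) <= pmin(ka, kd)))
})

test_that("standard-state correction shifts by RT ln(Vm) per molecularity unit", {
  expect_equal(standard_state_correction(10, delta_molecularity = 0), 10)
  shift <- 10 - standard_state_correction(10, delta_molecularity = -1)
  expect_equal(shift, 1.89, tolerance = 0.005)            # RT ln(24.46)
  there <- standard_state_correction(10, delta_molecularity = -1)
  back <- standard_state_correction(there, delta_molecularity = -1,
                                    direction = "molar_to_atm")
  expect_equal(back, 10, tolerance = 1e-12)
})

test_that("kappa resolution prefers explicit, then Eckart, then Wigner", {
  base <- list(compound = "X", site = "O14-H", mechanism = "FHT",
               medium = "gas", protonation_state = "HA",
               activation_gibbs = 16, imaginary_frequency = 1400,
               forward_barrier = 6, reverse_barrier = 8,
               tunneling_coefficient = 195.2,
               reorganization_energy = NA, barrierless = FALSE)
  expect_equal(resolve_kappa(base),
               list(kappa = 195.2, method = "provided"))
  base$tunneling_coefficient <- NA
  r <- resolve_kappa(base)
  expect_identical(r$method, "eckart")
  expect_equal(r$kappa, eckart_kappa(6, 8, 1400), tolerance = 1e-6)
  base$forward_barrier <- NA
  expect_identical(resolve_kappa(base)$method, "wigner")
  base$imaginary_frequency <- NA
  expect_equal(resolve_kappa(base), list(kappa = 1, method = "unity"))
  base$mechanism <- "SET"
  base$tunneling_coefficient <- 50
  expect_equal(resolve_kappa(base)$kappa, 1)              # SET never tunnels
})

test_that("channel_rates caps barrierless channels and obeys the diffusion limit", {
  ts <- validate_ts(data.frame(
    compound = c("X", "X", "X"), site = "O14-H",
    mechanism = c("FHT", "FHT", "SET"),
    medium = c("gas", "water", "water"),
    protonation_state = c("HA", "HA", "A_minus"),
    activation_gibbs = c(16.7, 16.6, 2.3),
    tunneling_coefficient = c(195.2, 1664.7, NA),
    stringsAsFactors = FALSE))
  r <- channel_rates(ts)
  expect_true(all(r$kappa >= 1))
  expect_true(all(r$k_app[!is.na(r$k_diffusion)] <=
                    r$k_diffusion[!is.na(r$k_diffusion)]))
  expect_true(is.na(r$k_diffusion[r$medium == "gas"]))
  expect_identical(r$kappa_method,
                   c("provided", "provided", "unity"))

  ts$barrierless <- c(TRUE, FALSE, FALSE)
  expect_warning(r2 <- channel_rates(ts, gas_collision_cap = 1e10),
                 "barrierless")
  expect_equal(r2$k_app[1], 1e10)
})
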