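test_that("tube law identities and exact inverse", {
  w <- ref_wall()
  expect_equal(tube_law(w$A0, w), w$P0)
  expect_equal(tube_law(4 * w$A0, w), w$P0 + w$beta)  # sqrt(4) - 1 = 1
  set.seed(1)
  A <- w$A0 * runif(100, 0.3, 3)
  expect_equal(tube_law_inv(tube_law(A, w), w), A, tolerance = 1e-12)
  expect_error(tube_law(-1, w), "non-positive")
  expect_error(tube_law_inv(w$P0 - 2 * w$beta, w), "collapse")
})

test_that("wave speed matches the Moens-Korteweg closed form and scalings", {
  w <- ref_wall(E = 4e5, r0 = 3, h0 = 0.3, sigma = 0.5)
  fl <- ref_fluid()
  c0 <- wave_speed(w$A0, w, fl)
  expect_equal(c0, sqrt(4e5 * 0.3e-3 / (2 * 1060 * 3e-3 * 0.75)),
               tolerance = 1e-12)
  expect_equal(c0, 5.02, tolerance = 2e-3)
  expect_equal(wave_speed(4 * w$A0, w, fl) / c0, sqrt(sqrt(4)),
               tolerance = 1e-12)
  fl4 <- ref_fluid(rho = 4 * 1060)
  expect_equal(wave_speed(w$A0, w, fl4), c0 / 2, tolerance = 1e-12)
})

test_that("a uniform rest state is a discrete equilibrium", {
  w <- ref_wall()
  fl <- ref_fluid()
  st <- vessel_state(s = 0:50, A = rep(w$A0, 51), Q = rep(0, 51), w)
  st2 <- advance_step(st, w, fl, dt = 5e-5)
  expect_lt(max(abs(st2$A - st$A)), 1e-14)
  expect_lt(max(abs(st2$Q)), 1e-14)
})

test_that("CFL violations are rejected with a suggested step", {
  w <- ref_wall()
  fl <- ref_fluid()
  st <- vessel_state(s = 0:50, A = rep(w$A0, 51), Q = rep(0, 51), w)
  expect_error(advance_step(st, w, fl, dt = 1e-3), "CFL violation")
})

test_that("Windkessel terminal matches its closed forms", {
  R1 <- 1e8; R2 <- 1e9; C <- 3e-10; Pout <- mmHg_to_Pa(5)
  Q0 <- 5e-6
  wk <- windkessel_state(R1, R2, C, Pout)
  dt <- 1e-4
  for (i in seq_len(2e5)) {  # t = 20 s >> R2 C = 0.3 s
    st <- windkessel_step(Q0, wk, dt)
    wk <- st$wk
  }
  expect_equal(st$P, Pout + Q0 * (R1 + R2), tolerance = 1e-2)

  # zero inflow from the rest state stays at rest
  wk0 <- windkessel_state(R1, R2, C, Pout)
  st0 <- windkessel_step(0, wk0, dt)
  expect_equal(st0$P, Pout, tolerance = 1e-12)

  # relaxation follows exp(-t/(R2 C)) at small dt
  wk1 <- windkessel_state(R1, R2, C, Pout, Pc = Pout + 1000)
  n <- 3000
  for (i in seq_len(n)) wk1 <- windkessel_step(0, wk1, dt)$wk
  expect_equal((wk1$Pc - Pout) / 1000, exp(-n * dt / (R2 * C)),
               tolerance = 1e-2)
})

test_that("the Young stenosis element has the stated structure", {
  fl <- ref_fluid()
  A0 <- 28.3
  # zero severity: turbulent term vanishes, drop is linear in Q
  s0 <- stenosis_element(A0_sten = A0, severity = 0, Ls = 10)
  expect_equal(stenosis_pressure_drop(2, 0, s0, fl) /
                 stenosis_pressure_drop(1, 0, s0, fl), 2, tolerance = 1e-12)
  # and reduces to the Poiseuille drop of an Ls-long tube
  r0 <- sqrt(A0 / pi)
  expect_equal(stenosis_pressure_drop(5, 0, s0, fl),
               8 * fl$mu * 0.01 * 5e-6 / (pi * (r0 * 1e-3)^4),
               tolerance = 1e-12)

  # severity 0.9: turbulent coefficient scales as (1/0.1 - 1)^2 = 81
  s9 <- stenosis_element(A0_sten = A0, severity = 0.9, Ls = 10)
  s5 <- stenosis_element(A0_sten = A0, severity = 0.5, Ls = 10)
  turb <- function(s) {
    co <- vasculate:::stenosis_si_coefficients(s, fl)
    co$kt
  }
  expect_equal(turb(s9) / turb(s5), 81, tolerance = 1e-12)

  # odd symmetry in Q for viscous + turbulent terms
  expect_equal(stenosis_pressure_drop(-5, 0, s9, fl),
               -stenosis_pressure_drop(5, 0, s9, fl), tolerance = 1e-12)
  expect_error(stenosis_element(A0_sten = A0, As = -1), "As")
})

test_that("grid refinement leaves the propagating pulse unchanged to 1%", {
  w <- ref_wall()
  fl <- ref_fluid(KR = 1e-30)
  c0 <- wave_speed(w$A0, w, fl)
  run <- function(ds) {
    L <- 200
    s <- seq(0, L, ds)
    A <- w$A0 * (1 + 0.01 * exp(-((s - 60) / 8)^2))
    u <- 4 * (wave_speed(A, w, fl) - c0)
    out <- simulate_tube(w, fl, L, t_end = 0.015, ds = ds, A0_init = A,
                         Q_init = u * A, n_out = 15)
    max(out$P)
  }
  p1 <- run(1)
  p05 <- run(0.5)
  expect_lt(abs(p1 - p05) / abs(p05 - mmHg_to_Pa(85)), 0.01)
})

test_that("a non-reflecting outlet passes the pulse with < 2% reflection", {
  w <- ref_wall()
  fl <- ref_fluid(KR = 1e-30)
  c0 <- wave_speed(w$A0, w, fl)
  L <- 150
  s <- seq(0, L, 1)
  amp <- 0.01
  A <- w$A0 * (1 + amp * exp(-((s - 75) / 8)^2))
  u <- 4 * (wave_speed(A, w, fl) - c0)
  # t long enough for the pulse to cross the right boundary completely
  out <- simulate_tube(w, fl, L, t_end = 0.035, ds = 1, A0_init = A,
                       Q_init = u * A, n_out = 35)
  residual <- max(abs(out$A[nrow(out$A), ] - w$A0))
  expect_lt(residual, 0.02 * amp * w$A0)
})
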