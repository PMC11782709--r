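mk_ens <- function(n_slice = 1, n_spoiler = 1, tissue = tissue_p2(),
                   pulse = rf_pulse_hard(90)) {
  equilibrium_ensemble(tissue, n_slice, n_spoiler, pulse)
}

mag_vec <- function(ens) sqrt(Mod(ens$mxy)^2 + ens$mz^2)

test_that("equilibrium ensemble starts at (0, 0, M0) with uniform spoiler grid", {
  ens <- mk_ens(1, 4)
  expect_equal(ens$mxy, complex(real = rep(0, 4)))
  expect_equal(ens$mz, rep(1, 4))
  expect_equal(sort(unique(mk_ens(2, 4)$spoiler_coord)), c(0, 0.25, 0.5, 0.75))
  big <- equilibrium_ensemble(tissue_p2(), 33, 20)
  expect_length(big$mz, 660)
  expect_true(all(big$mz == 1))
})

test_that("RF rotation follows the declared convention and preserves norm", {
  ens <- apply_rf(mk_ens(), rf_phase = 0)          # 90 deg: +z -> +y
  expect_equal(ens$mxy, complex(real = 0, imaginary = 1), tolerance = 1e-12)
  expect_equal(ens$mz, 0, tolerance = 1e-12)

  e10 <- apply_rf(mk_ens(pulse = rf_pulse_hard(10)))
  expect_equal(e10$mz, cos(10 * pi / 180))
  expect_equal(Mod(e10$mxy), sin(10 * pi / 180))

  # tiny flip approximates the identity
  e0 <- apply_rf(mk_ens(pulse = rf_pulse(1, 1e-9)))
  expect_equal(e0$mz, 1, tolerance = 1e-9)
  expect_equal(mag_vec(e10), 1, tolerance = 1e-12)
})

test_that("relaxation follows the closed-form exponentials", {
  ens <- mk_ens(tissue = tissue_properties(720, 40))
  expect_equal(relax(ens, 0)$mz, ens$mz)
  tipped <- apply_rf(ens)                          # (0, 1, 0)
  r <- relax(tipped, 40)
  expect_equal(Mod(r$mxy), exp(-1), tolerance = 1e-12)
  expect_equal(r$mz, 1 - exp(-40 / 720), tolerance = 1e-12)
  r_inf <- relax(tipped, 1e9)
  expect_equal(r_inf$mz, 1, tolerance = 1e-12)
  expect_error(relax(ens, -1), "non-negative")
})

test_that("precession is additive and leaves Mz alone", {
  ens <- apply_rf(mk_ens())                        # (0, 1, 0)
  p <- precess_phase(ens, -pi / 2)
  expect_equal(p$mxy, complex(real = 1, imaginary = 0), tolerance = 1e-12)
  two_step <- precess_phase(precess_phase(ens, 0.31), 0.55)
  one_step <- precess_phase(ens, 0.86)
  expect_equal(two_step$mxy, one_step$mxy, tolerance = 1e-12)
  expect_equal(precess_phase(ens, 2 * pi)$mxy, ens$mxy, tolerance = 1e-12)
  expect_equal(p$mz, ens$mz)
})

test_that("gradient spoiling dephases 2*pi per call and accumulates", {
  ens1 <- mk_ens(1, 1)
  expect_equal(spoil_gradient(apply_rf(ens1))$mxy, apply_rf(ens1)$mxy)

  ens20 <- apply_rf(mk_ens(1, 20))                 # uniform transverse
  expect_equal(sum(spoil_gradient(ens20)$mxy), 0 + 0i, tolerance = 1e-12)

  # two spoils equal direct 4*pi phase bookkeeping
  twice <- spoil_gradient(spoil_gradient(ens20))
  direct <- ens20
  direct$mxy <- direct$mxy * exp(4i * pi * direct$spoiler_coord)
  expect_equal(twice$mxy, direct$mxy, tolerance = 1e-12)
})

test_that("read_signal is the demodulated isochromat mean", {
  ens <- apply_rf(mk_ens(1, 5))                    # all at (0, 1, 0)
  expect_equal(read_signal(ens, receiver_phase = 90), 1 + 0i, tolerance = 1e-12)
  expect_equal(read_signal(mk_ens(1, 5)), 0 + 0i)

  set.seed(7)
  ens$mxy <- complex(real = rnorm(5), imaginary = rnorm(5))
  psi <- 37
  oracle <- 0 + 0i
  for (j in 1:5) oracle <- oracle + ens$mxy[j] * exp(-1i * psi * pi / 180)
  expect_equal(read_signal(ens, psi), oracle / 5, tolerance = 1e-12)
})

test_that("random operator sequences match a rotation-matrix oracle", {
  rz <- function(th) matrix(c(cos(th), sin(th), 0,
                              -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a),
                             0, sin(a), cos(a)), 3, 3)
  rf_mat <- function(a, psi) rz(psi) %*% rx(a) %*% rz(-psi)

  set.seed(42)
  for (rep in 1:50) {
    n <- sample(1:10, 1)
    ens <- equilibrium_ensemble(tissue_properties(900, 80), 1, n,
                                rf_pulse_hard(sample(5:90, 1)))
    M <- rbind(Re(ens$mxy), Im(ens$mxy), ens$mz)
    for (step in seq_len(sample(3:8, 1))) {
      op <- sample(c("rf", "relax", "precess", "spoil"), 1)
      if (op == "rf") {
        psi <- stats::runif(1, 0, 360)
        ens <- apply_rf(ens, psi)
        a <- ens$nominal_flip * pi / 180
        for (j in 1:n) M[, j] <- rf_mat(a, psi * pi / 180) %*% M[, j]
      } else if (op == "relax") {
        dt <- stats::runif(1, 0, 50)
        ens <- relax(ens, dt)
        e2 <- exp(-dt / 80); e1 <- exp(-dt / 900)
        M[1:2, ] <- M[1:2, ] * e2
        M[3, ] <- 1 + (M[3, ] - 1) * e1
      } else if (op == "precess") {
        phi <- stats::runif(1, -pi, pi)
        ens <- precess_phase(ens, phi)
        for (j in 1:n) M[1:2, j] <- rz(phi)[1:2, 1:2] %*% M[1:2, j]
      } else {
        ens <- spoil_gradient(ens)
        for (j in 1:n) {
          th <- 2 * pi * ens$spoiler_coord[j]
          M[1:2, j] <- rz(th)[1:2, 1:2] %*% M[1:2, j]
        }
      }
    }
    expect_equal(Re(ens$mxy), unname(M[1, ]), tolerance = 1e-10)
    expect_equal(Im(ens$mxy), unname(M[2, ]), tolerance = 1e-10)
    expect_equal(ens$mz, unname(M[3, ]), tolerance = 1e-10)
    expect_true(all(mag_vec(ens) <= 1 + 1e-9))  # norm bound from equilibrium
  }
})

test_that("perfect spoiling reaches the Ernst steady-state magnitude", {
  tis <- tissue_properties(2000, 160)
  cfg <- sequence_config(flip = 10, spoiling = "perfect",
                         n_slice = 1, n_spoiler = 1,
                         pulse = rf_pulse_hard(10),
                         n_tr_per_cycle = 150, n_cycles = 25)
  trace <- run_sequence(cfg, tis, bg = 0)
  s_ss <- Mod(tail(trace$signal, 1))
  expected <- ernst_signal(10, cfg$tr, 2000) * exp(-cfg$te / 160)
  expect_equal(s_ss, expected, tolerance = 1e-9)
})

test_that("ensemble serializes to a tidy magnetization table", {
  tb <- tibble::as_tibble(mk_ens(3, 2))
  expect_named(tb, c("slice_coord", "spoiler_coord", "flip_scale",
                     "Mx", "My", "Mz"))
  expect_equal(nrow(tb), 6)
  expect_true(all(tb$Mz == 1))
})
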