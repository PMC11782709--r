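test_that("FLASH RF-phase schedule follows the quadratic recurrence", {
  # direct recurrence oracle: phi_k = phi_{k-1} + k * 50
  inc <- 50
  phi <- numeric(5); for (k in 1:4) phi[k + 1] <- phi[k] + k * inc
  expect_equal(phi, c(0, 50, 150, 300, 500))
  sched <- pcsteady:::rf_phase_schedule(5, inc) * 180 / pi
  expect_equal(sched %% 360, phi %% 360, tolerance = 1e-9)
  expect_equal((phi %% 360)[5], 140)
  # long-run congruence with the unreduced recurrence
  n <- 500
  full <- cumsum(c(0, seq_len(n - 1)) * inc)
  expect_equal(cos(pcsteady:::rf_phase_schedule(n, inc)),
               cos(full * pi / 180), tolerance = 1e-6)
})

test_that("encoding labels follow the interleave mode and trigger structure", {
  cfg <- quick_config(n_tr_per_cycle = 6, n_trigger_tr = 2, n_cycles = 4,
                      interleave = "ECG")
  tr <- run_sequence(cfg, tissue_p1(), bg = 0)
  # ECG: whole cycles share one label, cycles alternate starting compensated
  lab <- tapply(tr$encoded, tr$cycle, unique)
  expect_equal(as.logical(lab), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(sum(!tr$in_window), 4 * 2)
  expect_true(all(tr$tr_in_cycle[!tr$in_window] <= 2))

  cfg_tr <- quick_config(n_tr_per_cycle = 6, n_trigger_tr = 2, n_cycles = 2,
                         interleave = "TR")
  tt <- run_sequence(cfg_tr, tissue_p1(), bg = 0)
  expect_equal(tt$encoded, rep(c(FALSE, TRUE), 6))
})

test_that("zero background phase gives zero phase contrast in all four modes", {
  # FISP: with no injected phase the complex signal stays on a fixed phase
  # axis (spoiler grid is reflection-symmetric), so the identity is exact
  for (il in c("TR", "ECG")) {
    cfg <- quick_config(contrast = "FISP", interleave = il)
    s <- phase_contrast(run_sequence(cfg, tissue_p2(), bg = 0))
    expect_lt(max(abs(s$dphi_rad)), 1e-10)
  }
  # FLASH: imperfect RF spoiling leaves a small TR-to-TR phase jitter even
  # at zero input; it averages out but is not pointwise zero
  for (il in c("TR", "ECG")) {
    cfg <- sequence_config(contrast = "FLASH", interleave = il,
                           n_cycles = if (il == "ECG") 6L else 3L,
                           n_slice = 17, n_spoiler = 128)
    s <- phase_contrast(run_sequence(cfg, tissue_p2(), bg = 0))
    # two orders of magnitude below the FISP steady-state effects studied
    expect_lt(abs(steady_state_deviation(s, 0)), 1e-2)
    last <- dplyr::filter(s, .data$cycle == max(.data$cycle))
    expect_lt(max(abs(last$dphi_rad)), 1e-2)
  }
})

test_that("perfect spoiling reproduces the injected phase exactly", {
  for (il in c("TR", "ECG")) {
    cfg <- quick_config(interleave = il, spoiling = "perfect")
    s <- phase_contrast(run_sequence(cfg, tissue_p2(), bg = 5))
    expect_equal(s$dphi_rad, rep(0.05 * pi, nrow(s)), tolerance = 1e-12)
    s10 <- phase_contrast(run_sequence(cfg, tissue_p2(), bg = 10))
    expect_equal(unique(round(s10$pct_venc, 9)), 10)
  }
})

test_that("TR-interleaved phase contrast settles into a steady state", {
  cfg <- study_config(contrast = "FISP", interleave = "TR", n_cycles = 7)
  s <- phase_contrast(run_sequence(cfg, tissue_p2(), bg = 10))
  # practically steady one cycle in (pair-to-pair drift < 1e-4 rad,
  # i.e. < 0.004 %venc), converging further as the transient dies out
  v2 <- max(abs(diff(dplyr::filter(s, .data$cycle == 2)$dphi_rad)))
  v7 <- max(abs(diff(dplyr::filter(s, .data$cycle == 7)$dphi_rad)))
  expect_lt(v2, 1e-4)
  expect_lt(v7, 1e-6)
  expect_lt(v7, v2)
})

test_that("ECG-mode pairing matches an exhaustive hand enumeration", {
  cfg <- quick_config(n_tr_per_cycle = 6, n_trigger_tr = 2, n_cycles = 4,
                      interleave = "ECG")
  tr <- run_sequence(cfg, tissue_p2(), bg = 3)
  s <- phase_contrast(tr)
  # cycles: 1 comp, 2 enc, 3 comp, 4 enc; windows are TRs 3..6 of each cycle.
  # encoded cycle 2 pairs with compensated cycle 1, 4 with 3, index by index.
  expect_equal(unique(s$pair), c(1L, 2L))
  expect_equal(unique(s$cycle), c(2L, 4L))
  expect_equal(s$phase_index, rep(1:4, 2))
  sig <- matrix(tr$signal, nrow = 6)   # column = cycle
  manual <- c(Arg(sig[3:6, 2] * Conj(sig[3:6, 1])),
              Arg(sig[3:6, 4] * Conj(sig[3:6, 3])))
  expect_equal(s$dphi_rad, manual, tolerance = 1e-12)
})

test_that("reported %venc is venc-independent while cm/s scales", {
  cfg30 <- quick_config(venc = 30)
  cfg60 <- quick_config(venc = 60)
  s30 <- phase_contrast(run_sequence(cfg30, tissue_p2(), bg = 8))
  s60 <- phase_contrast(run_sequence(cfg60, tissue_p2(), bg = 8))
  expect_equal(s30$pct_venc, s60$pct_venc, tolerance = 1e-12)
  expect_equal(s60$velocity_cms, 2 * s30$velocity_cms, tolerance = 1e-12)
})

test_that("ECG mode refuses single-cycle runs and deviation checks series length", {
  cfg <- quick_config(interleave = "ECG", n_cycles = 1)
  expect_error(run_sequence(cfg, tissue_p2(), bg = 0), "at least 2 cycles")
  s <- phase_contrast(run_sequence(quick_config(), tissue_p2(), bg = 0))
  expect_error(steady_state_deviation(s, 0, n_avg = nrow(s) + 1), "at least")
})

test_that("ideal spoiled reference carries Ernst magnitude and the injected phase", {
  cfg <- study_config(contrast = "FLASH", n_cycles = 2)
  tis <- tissue_p2()
  ref <- ideal_spoiled_reference(cfg, tis, bg = 7)
  expect_equal(unique(ref$pct_venc), 7)
  m_expect <- ernst_signal(cfg$flip, cfg$tr, tis$t1) * exp(-cfg$te / tis$t2)
  expect_equal(unique(ref$magnitude), m_expect, tolerance = 1e-12)
  # Ernst angle maximizes the closed-form magnitude over integer flips
  e1 <- exp(-cfg$tr / tis$t1)
  ernst_deg <- acos(e1) * 180 / pi
  mags <- vapply(1:90, function(f) ernst_signal(f, cfg$tr, tis$t1), numeric(1))
  expect_equal(which.max(mags), round(ernst_deg))
})
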