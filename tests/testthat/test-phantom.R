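# a tiny scene + short sequence keeps renders around a second
tiny_scene <- function(preset = "P2_offcenter", ...) {
  grid <- if (preset == "vessel_demo") image_grid(12, 12, 48)
          else image_grid(16, 8, c(370, 160))
  make_scene(preset, grid = grid, ...)
}
render_cfg <- function(...) {
  defaults <- list(n_tr_per_cycle = 24, n_trigger_tr = 4, n_cycles = 4,
                   n_slice = 5, n_spoiler = 16, venc = 60)
  do.call(sequence_config, utils::modifyList(defaults, list(...)))
}

test_that("phantom presets carry the measured gel relaxation times", {
  p1 <- make_scene("P1_offcenter")
  expect_equal(p1$tissue_table[["1"]]$t1, 720)
  expect_equal(p1$tissue_table[["1"]]$t2, 40)
  p2 <- make_scene("P2_offcenter")
  expect_equal(p2$tissue_table[["1"]]$t1, 2000)
  expect_equal(p2$tissue_table[["1"]]$t2, 160)
  # 115 mm disc shifted 120 mm: no tissue at the isocenter pixel block
  xy <- pcsteady:::grid_coords(p2$grid)
  centre <- which(abs(xy$x_mm) < p2$grid$px_mm[1] & abs(xy$y_mm) < p2$grid$px_mm[2])
  expect_true(all(p2$tissue_map[centre] == 0))
  expect_error(make_scene("unknown"), "arg")
})

test_that("zero background field renders identically zero phase difference", {
  sc <- tiny_scene(bg_field = polynomial_field())
  st <- render_timeseries(sc, render_cfg())
  expect_lt(max(abs(velocity_map(st))), 1e-10)
  expect_equal(max(abs(st$truth_bg)), 0)
})

test_that("noiseless render equals the direct single-voxel simulation pixelwise", {
  sc <- tiny_scene()
  cfg <- render_cfg()
  st <- render_timeseries(sc, cfg, bg_quant = 0, n_phases = NULL)
  bg_map <- pcsteady:::eval_field_grid(sc$bg_field, sc$grid)
  pix <- which(sc$tissue_map == 1)
  for (p in sample(pix, 3)) {
    trace <- run_sequence(cfg, sc$tissue_table[["1"]], bg = bg_map[[p]])
    pairs <- pcsteady:::readout_pairs(trace, cfg)
    iy <- (p - 1) %% sc$grid$ny + 1; ix <- (p - 1) %/% sc$grid$ny + 1
    expect_equal(st$enc[iy, ix, ], pairs$s_enc, tolerance = 1e-10)
    expect_equal(st$comp[iy, ix, ], pairs$s_comp, tolerance = 1e-10)
    got_phase <- Arg(st$enc[iy, ix, ] * Conj(st$comp[iy, ix, ]))
    want <- tail(phase_contrast(trace)$dphi_rad, length(got_phase))
    expect_equal(got_phase, want, tolerance = 1e-10)
  }
})

test_that("bg-field cache changes nothing beyond the quantization step", {
  sc <- tiny_scene()
  cfg <- render_cfg()
  exact <- render_timeseries(sc, cfg, bg_quant = 0, n_phases = NULL)
  cached <- render_timeseries(sc, cfg, bg_quant = 0.05, n_phases = NULL)
  dv <- abs(velocity_map(exact) - velocity_map(cached))
  # 0.05 %venc quantization bounds the injected-phase error per pixel
  expect_lt(max(dv), 0.05 / 100 * cfg$venc * 2)
})

test_that("renders are bit-reproducible for a fixed seed", {
  sc <- tiny_scene(noise_sigma = 0.01, seed = 33L)
  cfg <- render_cfg()
  a <- render_timeseries(sc, cfg)
  b <- render_timeseries(sc, cfg)
  expect_identical(a$enc, b$enc)
  expect_identical(a$comp, b$comp)
  sc2 <- tiny_scene(noise_sigma = 0.01, seed = 34L)
  expect_false(identical(render_timeseries(sc2, cfg)$enc, a$enc))
})

test_that("fresh-spin vessels measure exactly the encoded flow phase", {
  sc <- tiny_scene("vessel_demo", bg_field = polynomial_field())
  cfg <- render_cfg()
  st <- render_timeseries(sc, cfg, bg_quant = 0, n_phases = NULL,
                          vessel_mode = "fresh")
  v <- velocity_map(st)
  frac <- (st$phases_ms / cfg$tr) / cfg$n_tr_per_cycle
  expected <- sc$velocity_waveform(frac)
  for (p in which(sc$vessel_mask)) {
    iy <- (p - 1) %% sc$grid$ny + 1; ix <- (p - 1) %/% sc$grid$ny + 1
    expect_equal(v[iy, ix, ], expected, tolerance = 1e-9)
  }
})

test_that("velocity at or above venc is rejected", {
  sc <- tiny_scene("vessel_demo", vessel_velocity = 70)
  expect_error(render_timeseries(sc, render_cfg(venc = 60)), "venc")
})

test_that("phase-phase decimation averages consecutive pairs", {
  sc <- tiny_scene()
  cfg <- render_cfg()
  full <- render_timeseries(sc, cfg, n_phases = NULL)
  np <- length(full$phases_ms)
  half <- render_timeseries(sc, cfg, n_phases = np %/% 2)
  expect_equal(dim(half$enc)[3], np %/% 2)
  iy <- which(sc$tissue_map == 1)[1]
  p <- iy  # column-major index of a tissue pixel
  yy <- (p - 1) %% sc$grid$ny + 1; xx <- (p - 1) %/% sc$grid$ny + 1
  expect_equal(half$enc[yy, xx, 1],
               mean(full$enc[yy, xx, 1:2]), tolerance = 1e-12)
  expect_equal(half$phases_ms[1], mean(full$phases_ms[1:2]))
})

test_that("stacks round-trip losslessly through NIfTI plus sidecar", {
  sc <- tiny_scene(noise_sigma = 0.005, seed = 7L)
  st <- render_timeseries(sc, render_cfg())
  prefix <- file.path(withr::local_tempdir(), "stack")
  save_stack(st, prefix)
  back <- load_stack(prefix)
  expect_identical(back$comp, st$comp)
  expect_identical(back$enc, st$enc)
  expect_equal(back$venc, st$venc)
  expect_equal(back$phases_ms, st$phases_ms)
  # exported phase volumes stay within (-pi, pi]
  ph <- RNifti::readNifti(paste0(prefix, "_phase_enc.nii"))
  expect_true(all(ph > -pi - 1e-12 & ph <= pi + 1e-12))
  # sidecar with a missing field is rejected by name
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  meta$venc <- NULL
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE)
  expect_error(load_stack(prefix), "venc", class = "pcsteady_parse_error")
})
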