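## Phantom fixtures are built once per file: a straight tube with the
## default pulsatile waveform and a three-phase constant-flow tube.

wf20 <- generate_waveform(waveform_params(noise_sd = 0), 20)
tube <- straight_phantom(length_mm = 8, radius = 2.5, voxel_size = 0.5)
field <- build_phantom(tube, wf20)

const_wf <- flow_waveform(seq(0, 1, length.out = 4)[1:3], rep(5, 3), 1)
tube2 <- straight_phantom(length_mm = 5, radius = 2, voxel_size = 0.5)
field2 <- build_phantom(tube2, const_wf)

test_that("phantom geometry invariants are enforced", {
  expect_error(vessel_phantom(cbind(1:10, 5, 5), radius = 0.6,
                              voxel_size = 0.5, grid_shape = c(20, 20, 20)),
               ">= 2 voxels")
  expect_error(vessel_phantom(cbind(c(1, 3), 5, 5), radius = 2,
                              voxel_size = 0.5, grid_shape = c(20, 20, 20)),
               "1 voxel apart")
  pts <- cbind(seq(0.5, 5, by = 0.5), 1, 1)  # too close to the boundary
  expect_error(vessel_phantom(pts, radius = 2, voxel_size = 0.5,
                              grid_shape = c(20, 8, 8)), "boundary")
})

test_that("Poiseuille construction: apex velocity, no-slip wall, exact flow", {
  r_cm <- tube$radius / 10
  q <- wf20$flow_rates
  ## apex: centerline voxel speed = 2Q/(pi R^2) at every phase
  mid <- ceiling(nrow(tube$centerline_points) / 2)
  pt <- tube$centerline_points[mid, ]
  ijk <- pmax(1, round(pt / tube$voxel_size + 0.5))
  ## the voxel containing the centerline sits within half a voxel of the
  ## axis; its speed is within the profile variation of the apex value
  for (ph in c(1, which.max(q))) {
    v <- abs(field$vx[ijk[1], ijk[2], ijk[3], ph])
    apex <- 2 * q[ph] / (pi * r_cm^2)
    expect_equal(v, apex, tolerance = 0.02)
  }
  ## no-slip: voxels outside the lumen carry zero velocity
  edge <- field$vx[1, 1, 1, ]
  expect_equal(edge, rep(0, 20))
  ## analytic cross-section integral of the parabolic profile returns Q
  ## exactly: verified numerically through cross_section_flow below
  expect_equal(field$n_phases, 20)
})

test_that("VENC guard rejects super-VENC construction unless aliasing wraps", {
  hot <- flow_waveform(seq(0, 1, length.out = 4)[1:3], rep(60, 3), 1)
  expect_error(build_phantom(tube2, hot, venc = 110), "exceeds VENC")
  wrapped <- build_phantom(tube2, hot, venc = 110, aliasing = TRUE)
  expect_true(max(abs(wrapped$vx)) <= 110)
})

test_that("cross-section flow recovers the construction truth within 3%", {
  tg <- flowpulse:::centerline_tangents(tube2$centerline_points)
  mid <- ceiling(nrow(tube2$centerline_points) / 2)
  f <- cross_section_flow(field2, tube2$centerline_points[mid, ], tg[mid, ],
                          phase = 1, max_radius = 2 * tube2$radius)
  expect_equal(f, 5, tolerance = 0.03)
  ## zero-flow phase gives zero
  zero_wf <- flow_waveform(seq(0, 1, length.out = 4)[1:3], c(5, 0, 5), 1)
  fz <- build_phantom(tube2, zero_wf)
  expect_equal(cross_section_flow(fz, tube2$centerline_points[mid, ],
                                  tg[mid, ], phase = 2), 0)
  ## doubling the waveform doubles the flow at every phase (linearity)
  dbl <- build_phantom(tube2, flow_waveform(seq(0, 1, length.out = 4)[1:3],
                                            rep(10, 3), 1), venc = 200)
  f2 <- cross_section_flow(dbl, tube2$centerline_points[mid, ], tg[mid, ],
                           phase = 1)
  expect_equal(f2, 2 * f, tolerance = 1e-12)
  expect_error(cross_section_flow(field2, c(-5, 0, 0), c(1, 0, 0), 1),
               "outside the grid")
})

test_that("flow is conserved along the tube and error halves on refinement", {
  ## conservation: all six window voxels, all 20 phases, within 3% of truth
  start <- 6
  tg <- flowpulse:::centerline_tangents(tube$centerline_points)
  for (i in start:(start + 5)) {
    fl <- vapply(1:20, function(ph) {
      cross_section_flow(field, tube$centerline_points[i, ], tg[i, ], ph,
                         max_radius = 1.5 * tube$radius)
    }, numeric(1))
    expect_lt(max(abs(fl - wf20$flow_rates) / abs(wf20$flow_rates)), 0.03)
  }
  ## refinement: halving the voxel size at least halves the error
  err <- vapply(c(0.5, 0.25), function(v) {
    ph <- straight_phantom(length_mm = 5, radius = 2, voxel_size = v)
    fd <- build_phantom(ph, const_wf)
    tgs <- flowpulse:::centerline_tangents(ph$centerline_points)
    mid <- ceiling(nrow(ph$centerline_points) / 2)
    abs(cross_section_flow(fd, ph$centerline_points[mid, ], tgs[mid, ], 1,
                           max_radius = 2 * 2) - 5) / 5
  }, numeric(1))
  expect_lt(err[2], err[1] / 2)
})

test_that("six-voxel centerline extraction averages and matches truth", {
  ex <- extract_centerline_flow(field, tube, start_voxel = 6)
  expect_s3_class(ex, "flow_waveform")
  expect_equal(ex$flow_rates, wf20$flow_rates, tolerance = 0.01)
  expect_equal(ex$rr_interval, wf20$rr_interval)
  ## window must fit on the centerline
  expect_error(extract_centerline_flow(field, tube, start_voxel = 100),
               "centerline voxels")
  ## curved tube agrees with the straight tube within 5%
  bend <- curved_phantom(bend_radius = 20, arc_deg = 45, radius = 2.5,
                         voxel_size = 0.5)
  fb <- build_phantom(bend, wf20)
  exb <- extract_centerline_flow(fb, bend, start_voxel = 15)
  expect_lt(max(abs(exb$flow_rates - ex$flow_rates) / abs(ex$flow_rates)),
            0.05)
})

test_that("velocity fields round-trip through NIfTI plus JSON sidecar", {
  dir <- withr::local_tempdir()
  write_velocity_field(field2, dir)
  expect_true(all(file.exists(file.path(dir, c("vx.nii.gz", "vy.nii.gz",
                                               "vz.nii.gz", "field.json")))))
  back <- read_velocity_field(dir)
  expect_equal(back$vx, field2$vx, tolerance = 1e-6)
  expect_equal(back$venc, field2$venc)
  expect_equal(back$phase_times, field2$phase_times)
  expect_equal(back$grid_shape, field2$grid_shape)
})

test_that("end-to-end phantom pipeline recovers PI and FVP", {
  ## gating -> phantom -> six-voxel extraction -> metrics, against the
  ## dense ground truth of the same waveform model (moderate peak width,
  ## the regime 20 phases can resolve)
  p <- waveform_params(mean_flow = 4.5, pulse_amplitude = 4,
                       peak_width = 0.2, dicrotic_amplitude = 0.6,
                       noise_sd = 0)
  dense <- generate_waveform(p, 2000)
  rec <- gated_reconstruction(waveform_function(p), rr_sequence(p, 40),
                              n_phases = 20, n_acq = 6000, seed = 31)
  ph <- straight_phantom(length_mm = 8, radius = 2.5, voxel_size = 0.5)
  fd <- build_phantom(ph, rec)
  ex <- extract_centerline_flow(fd, ph, start_voxel = 6)
  m_true <- pulsatility_metrics(dense)
  m_ex <- pulsatility_metrics(ex)
  expect_lt(abs(m_ex$pi_raw - m_true$pi_raw) / m_true$pi_raw, 0.10)
  expect_lt(abs(m_ex$fvp_raw - m_true$fvp_raw) / m_true$fvp_raw, 0.05)
})
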