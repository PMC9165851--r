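test_that("projected thickness follows the shell/ball geometry", {
  m <- capsid_model(outer_radius_nm = 12.5, shell_thickness_nm = 2.5)
  # at the sphere edge the chord vanishes
  expect_equal(projected_thickness(12.5, m, "empty"), 0)
  expect_equal(projected_thickness(12.5, m, "full"), 0)
  expect_equal(projected_thickness(20, m, "full"), 0)
  # chord difference at the centre: 2 (R_o - R_i)
  expect_equal(projected_thickness(0, m, "empty"), 5.0)
  # full adds the interior ball chord at relative density 0.8
  expect_equal(projected_thickness(0, m, "full"), 5.0 + 0.8 * 20)
  expect_error(projected_thickness(0, m, "broken"))
  expect_error(projected_thickness(-1, m, "full"))
})

test_that("the empty-shell projection peaks at the inner radius", {
  m <- capsid_model(outer_radius_nm = 12.5, shell_thickness_nm = 2.5)
  # brute-force maximisation on a fine grid
  r <- seq(0, 12.5, by = 1e-4)
  t_emp <- projected_thickness(r, m, "empty")
  expect_equal(r[which.max(t_emp)], 10, tolerance = 1e-3)
  # the full-particle projection peaks at the centre
  t_full <- projected_thickness(r, m, "full")
  expect_equal(which.max(t_full), 1L)
})

test_that("capsid model and sim config enforce their invariants", {
  expect_error(capsid_model(shell_thickness_nm = 13), "shell_thickness")
  expect_error(capsid_model(shell_thickness_nm = 0), "shell_thickness")
  expect_error(capsid_model(interior_density_rel = -0.1), "interior_density")
  expect_error(sim_config(p_full = 1.2))
  expect_error(sim_config(pixel_size_nm = 0))
  # separation below one diameter is rejected at simulation time
  cfg <- sim_config(image_size_px = c(128, 128), pixel_size_nm = 1,
                    n_particles = 2, min_separation_nm = 20, seed = 1)
  expect_error(simulate_micrograph(cfg, capsid_model()), "min_separation")
})

test_that("simulation is deterministic and conserves the particle count", {
  cfg <- bench_sim_config(12, 0.5, seed = 42, image_size = 256)
  s1 <- simulate_micrograph(cfg, bench_model())
  s2 <- simulate_micrograph(cfg, bench_model())
  expect_identical(s1$micrograph$intensities, s2$micrograph$intensities)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$truth), 12L)
  # zero particles: pure background + noise, empty truth
  cfg0 <- bench_sim_config(0, 0.5, seed = 1, image_size = 64, noiseless = TRUE)
  s0 <- simulate_micrograph(cfg0, bench_model())
  expect_equal(nrow(s0$truth), 0L)
  expect_true(all(s0$micrograph$intensities == 100))
})

test_that("fixed-count mode draws exactly the nominal number of full capsids", {
  cfg <- bench_sim_config(20, 0.4, seed = 3, image_size = 512,
                          fixed_counts = TRUE)
  s <- simulate_micrograph(cfg, bench_model())
  expect_equal(sum(s$truth$class == "full"), 8L)
})

test_that("placement fails loudly when the frame cannot hold the particles", {
  cfg <- sim_config(image_size_px = c(128, 128), pixel_size_nm = 1,
                    n_particles = 40, min_separation_nm = 33, seed = 1)
  expect_error(simulate_micrograph(cfg, capsid_model()), "place")
})

test_that("a noiseless empty capsid is darkest on a ring at the inner radius", {
  cfg <- sim_config(image_size_px = c(256, 256), pixel_size_nm = 0.5,
                    n_particles = 1, p_full = 0, fixed_counts = TRUE,
                    noise_sd = 0, min_separation_nm = 25, seed = 9)
  s <- simulate_micrograph(cfg, capsid_model())
  img <- s$micrograph$intensities
  idx <- which(img == min(img), arr.ind = TRUE)
  r_px <- sqrt((idx[, 2] - 1 - s$truth$x_px)^2 + (idx[, 1] - 1 - s$truth$y_px)^2)
  # inner radius 10 nm = 20 px; rasterisation allows ~1 px slack
  expect_true(all(abs(r_px - 20) < 1.5))
})

test_that("azimuthal means track the analytic projection within 2% of range", {
  model <- capsid_model()
  for (cls in c("full", "empty")) {
    cfg <- sim_config(image_size_px = c(256, 256), pixel_size_nm = 0.5,
                      n_particles = 1, p_full = (cls == "full") * 1,
                      fixed_counts = TRUE, noise_sd = 0,
                      min_separation_nm = 25, seed = 4)
    s <- simulate_micrograph(cfg, model)
    img <- s$micrograph$intensities
    d_nm <- 0.5 * sqrt(outer((seq_len(256) - 1 - s$truth$y_px)^2,
                             (seq_len(256) - 1 - s$truth$x_px)^2, `+`))
    contrast_range <- 2 * projected_thickness(0, model, "full")
    for (bin in list(c(0, 2.5), c(5, 7.5), c(9, 11))) {
      sel <- d_nm >= bin[1] & d_nm < bin[2]
      # area-weighted analytic mean over the annulus
      f <- function(r) projected_thickness(r, model, cls) * r
      t_bar <- 2 * stats::integrate(f, bin[1], bin[2])$value /
        (bin[2]^2 - bin[1]^2)
      expect_equal(mean(img[sel]), 100 - 2 * t_bar,
                   tolerance = 0.02 * contrast_range / (100 - 2 * t_bar))
    }
  }
})

test_that("full capsid centres are darker than empty ones", {
  model <- capsid_model()
  mk <- function(p) {
    cfg <- sim_config(image_size_px = c(256, 256), pixel_size_nm = 0.5,
                      n_particles = 1, p_full = p, fixed_counts = TRUE,
                      noise_sd = 0, min_separation_nm = 25, seed = 5)
    simulate_micrograph(cfg, model)
  }
  central_mean <- function(s) {
    img <- s$micrograph$intensities
    d <- 0.5 * sqrt(outer((seq_len(256) - 1 - s$truth$y_px)^2,
                          (seq_len(256) - 1 - s$truth$x_px)^2, `+`))
    mean(img[d < 5])   # r < R_i / 2
  }
  expect_lt(central_mean(mk(1)), central_mean(mk(0)))
})

test_that("truth_to_picks produces a valid analysis-ready pick table", {
  cfg <- bench_sim_config(8, 0.5, seed = 2, image_size = 256)
  set <- simulate_image_set(cfg, bench_model(), n_images = 2)
  picks <- truth_to_picks(set$truth, 1)
  expect_equal(nrow(analysis_picks(picks)), 16L)
  expect_equal(unique(picks$radius_px), 12.5)
})
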