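test_that("percent full follows the counting rule with uncertain set aside", {
  expect_equal(percent_full(full = 0, empty = 100)$percent_full, 0)
  r <- percent_full(full = 10, empty = 90, uncertain = 5)
  expect_equal(r$percent_full, 10.0)
  expect_equal(r$denominator, 100)
  expect_error(percent_full(full = 0, empty = 0), "full \\+ empty")
  # optional mode: uncertain in the denominator
  r2 <- percent_full(full = 10, empty = 85, uncertain = 5,
                     uncertain_in_denominator = TRUE)
  expect_equal(r2$denominator, 100)
  # bookkeeping: all classes reported
  expect_equal(sum(r$counts), 105)
})

test_that("the Wilson interval matches its closed form", {
  # independent oracle: Wilson score interval evaluated directly
  wilson <- function(k, n, conf = 0.95) {
    z <- qnorm(1 - (1 - conf) / 2)
    p <- k / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    100 * c(centre - half, centre + half)
  }
  r <- percent_full(full = 750, empty = 750)
  expect_equal(r$percent_full, 50.0)
  expect_equal(r$ci_95, wilson(750, 1500), tolerance = 1e-10)
  expect_equal(round(r$ci_95, 1), c(47.5, 52.5))
  # interval contains the point estimate, also near the boundary
  r2 <- percent_full(full = 3, empty = 297)
  expect_true(r2$ci_95[1] <= r2$percent_full_raw &&
                r2$percent_full_raw <= r2$ci_95[2])
  expect_gt(r2$ci_95[1], 0)
})

test_that("reported percentages round half-up in both modes", {
  expect_equal(percent_full(full = 835, empty = 165,
                            rounding = "integer")$percent_full, 84)
  expect_equal(percent_full(full = 835, empty = 165,
                            rounding = "1dp")$percent_full, 83.5)
  expect_equal(percent_full(full = 1, empty = 7,
                            rounding = "1dp")$percent_full, 12.5)
})

test_that("sampling sd follows the binomial closed form and its scalings", {
  curve <- sample_size_study(n_grid = c(375, 1500, 6000), p_grid = c(0, 0.5),
                             replicates = 1000, seed = 3)
  z <- as.data.frame(curve)
  expect_true(all(z$sd_mc[z$p == 0] == 0))
  at <- function(n, p) z$sd_mc[z$n == n & z$p == p]
  # n = 1500, p = 0.5: within 10% of the 1.29-point closed form
  expect_equal(at(1500, 0.5), 100 * sqrt(0.25 / 1500), tolerance = 0.1)
  # sqrt(n) scaling: quadrupling n halves the sd (Monte-Carlo slack)
  expect_equal(at(6000, 0.5) / at(1500, 0.5), 0.5, tolerance = 0.15)
  # monotone decreasing in n at fixed p
  expect_true(all(diff(z$sd_mc[z$p == 0.5][order(z$n[z$p == 0.5])]) < 0))
  # maximal near p = 0.5
  curve2 <- sample_size_study(1500, c(0.1, 0.5, 0.9), 500, seed = 4)
  z2 <- as.data.frame(curve2)
  expect_equal(which.max(z2$sd_mc), 2L)
})

test_that("the pipeline estimate agrees with simulation truth", {
  cfg <- bench_sim_config(250, 0.6, snr = 5, seed = 77, image_size = 1024)
  set <- simulate_image_set(cfg, bench_model(), n_images = 3)
  rc <- run_config(min_particles = 700L)
  report <- estimate_from_pipeline(set$micrographs, rc)
  true_pct <- 100 * mean(set$truth$class == "full")
  expect_equal(report$percent_full_raw, true_pct, tolerance = 0.02)
  expect_equal(report$n_images, 3L)
  # denominator rule conserved
  expect_equal(sum(report$counts), report$denominator +
                 report$counts[["uncertain"]] + report$counts[["excluded"]])
  # identical rerun on the same images is bit-identical (RSD 0)
  report2 <- estimate_from_pipeline(set$micrographs, rc)
  expect_identical(report2$percent_full_raw, report$percent_full_raw)
})

test_that("the counting gate stops short datasets unless overridden", {
  cfg <- bench_sim_config(40, 0.5, snr = 5, seed = 78, image_size = 512)
  s <- simulate_micrograph(cfg, bench_model())
  rc <- run_config()
  expect_error(estimate_from_pipeline(list(s$micrograph), rc),
               "minimum counting rule")
  expect_warning(
    estimate_from_pipeline(list(s$micrograph), rc, allow_short = TRUE),
    "minimum counting rule")
})

test_that("percent-full recovery holds across the mixing range", {
  # classification from known centres at n = 1500; the estimate must sit
  # within 3 percentage points of the nominal mixing fraction
  for (p in c(0.01, 0.6)) {
    cfg <- bench_sim_config(300, p, snr = 5, seed = round(1000 * p) + 7,
                            image_size = 1024)
    set <- simulate_image_set(cfg, bench_model(), n_images = 5)
    out <- classify_from_truth(set)
    tab <- table(factor(out$labels, levels = c("full", "empty", "uncertain")))
    est <- percent_full(tab[["full"]], tab[["empty"]],
                        tab[["uncertain"]])$percent_full_raw
    expect_lt(abs(est - 100 * p), 3)
  }
})
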