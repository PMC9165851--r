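test_that("PCA requires variance and enough profiles, and fixes signs", {
  flatmat <- matrix(1, 20, 32)
  expect_error(fit_pca(flatmat), "zero total variance")
  expect_error(fit_pca(matrix(rnorm(5 * 32), 5)), "at least 10")
  # rank-1 data: amplitude-scaled fixed shape
  shape <- sin(seq(0, pi, length.out = 32))
  x <- outer(rnorm(40, 1, 0.3), shape)
  model <- fit_pca(x)
  expect_gte(model$var_explained[1], 0.999)
  # orthonormal loadings, non-increasing explained variance
  expect_equal(unname(crossprod(model$loadings)), diag(2), tolerance = 1e-8)
  expect_true(diff(model$var_explained) <= 0)
  # sign convention: central-bin loading is non-positive
  expect_lte(model$loadings[1, 1], 0)
  expect_lte(model$loadings[1, 2], 0)
})

test_that("full and empty capsids form separable clusters in PC space", {
  cfg <- bench_sim_config(200, 0.5, snr = 5, seed = 15, fixed_counts = TRUE,
                          image_size = 1024)
  set <- simulate_image_set(cfg, bench_model(), n_images = 2)
  pset <- profile_particles(set$micrographs, truth_to_picks(set$truth, 1))
  model <- fit_pca(pset)
  sc <- pca_scores(model, pset)
  expect_gt(silhouette_mean(sc, set$truth$class), 0.5)
})

test_that("noiseless classification recovers ground truth exactly", {
  cfg <- bench_sim_config(200, 0.5, seed = 11, noiseless = TRUE,
                          fixed_counts = TRUE, image_size = 1024)
  set <- simulate_image_set(cfg, bench_model(), n_images = 1)
  out <- classify_from_truth(set)
  expect_equal(rand_index_adjusted(out$labels, out$truth), 1)
  expect_equal(sum(out$labels == "uncertain"), 0L)
  expect_equal(out$labels, out$truth)
  expect_true(out$result$separated)
})

test_that("label semantics are anchored to central density, not cluster order", {
  # minority-full and minority-empty mixtures must both label correctly
  for (p in c(0.2, 0.8)) {
    cfg <- bench_sim_config(150, p, seed = 20 + 10 * p, noiseless = TRUE,
                            fixed_counts = TRUE, image_size = 1024)
    set <- simulate_image_set(cfg, bench_model(), n_images = 1)
    out <- classify_from_truth(set)
    expect_equal(out$labels, out$truth)
  }
})

test_that("single-population samples take the degenerate path", {
  cfg <- bench_sim_config(120, 0, snr = 5, seed = 31, image_size = 1024)
  set <- simulate_image_set(cfg, bench_model(), n_images = 1)
  picks <- truth_to_picks(set$truth, 1)
  pset <- profile_particles(set$micrographs, picks)
  model <- fit_pca(pset)
  expect_warning(
    res <- cluster_and_label(pca_scores(model, pset),
                             profile_summaries(pset)),
    "degenerate")
  expect_true(all(res$assignments$label == "empty"))
  expect_false(res$separated)
  # all-full sample labels full
  cfg2 <- bench_sim_config(120, 1, snr = 5, seed = 32, image_size = 1024)
  set2 <- simulate_image_set(cfg2, bench_model(), n_images = 1)
  pset2 <- profile_particles(set2$micrographs, truth_to_picks(set2$truth, 1))
  expect_warning(
    res2 <- cluster_and_label(pca_scores(fit_pca(pset2), pset2),
                              profile_summaries(pset2)),
    "degenerate")
  expect_true(all(res2$assignments$label == "full"))
})

test_that("the separation flag tracks cluster distance", {
  # synthetic score clouds with unit covariance at varying separation;
  # brute-force grid oracle for ellipse disjointness
  grid_disjoint <- function(delta, level = 0.99) {
    q <- stats::qchisq(level, 2)
    xs <- seq(-6, delta + 6, by = 0.05)
    ys <- seq(-6, 6, by = 0.05)
    in1 <- outer(ys^2, xs^2, `+`) <= q                 # unit-cov cluster at 0
    in2 <- outer(ys^2, (xs - delta)^2, `+`) <= q       # and at (delta, 0)
    !any(in1 & in2)
  }
  make <- function(delta, seed) withr::with_seed(seed, {
    n <- 300
    sc <- rbind(cbind(rnorm(n), rnorm(n)),
                cbind(rnorm(n) + delta, rnorm(n)))
    colnames(sc) <- c("pc1", "pc2")
    summaries <- data.frame(central = c(rep(-10, n), rep(-2, n)),
                            ring = rep(-4, 2 * n))
    cluster_and_label(sc, summaries)
  })
  res_far <- make(10, 41)
  res_near <- suppressWarnings(make(0.5, 42))  # may hit the degenerate path
  expect_true(res_far$separated)
  expect_true(grid_disjoint(10))
  expect_false(res_near$separated)
  expect_false(grid_disjoint(0.5))
  # monotone: once separated at some distance, larger distances stay separated
  # (small separations may collapse to the degenerate single-cluster path,
  # which also reports non-separation)
  flags <- vapply(c(2, 4, 6, 8, 12), function(d)
    suppressWarnings(make(d, 50 + d)$separated), logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))
})

test_that("manual assignment updates labels and provenance", {
  sc <- withr::with_seed(1, {
    s <- rbind(cbind(rnorm(50), rnorm(50)), cbind(rnorm(50) + 20, rnorm(50)))
    colnames(s) <- c("pc1", "pc2"); s
  })
  summ <- data.frame(central = c(rep(-12, 50), rep(-2, 50)),
                     ring = rep(-4, 100))
  res <- cluster_and_label(sc, summ, posterior_threshold = 0.99)
  n_full0 <- sum(res$assignments$label == "full")
  ids <- res$assignments$particle_id[res$assignments$label == "empty"][1:5]
  res2 <- manual_assign(res, ids, "full")
  expect_equal(sum(res2$assignments$label == "full"), n_full0 + 5)
  expect_true(all(res2$assignments$manual[match(ids, res2$assignments$particle_id)]))
  # empty selection: no-op
  expect_identical(manual_assign(res, integer(0), "full"), res)
  expect_error(manual_assign(res, ids, "partial"), "invalid label")
  expect_error(manual_assign(res, 9999, "full"), "unknown particle")
})
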