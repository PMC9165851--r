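# Shared builders for simulated fixtures. Benchmarks run at 1 nm/px on
# modest frames; physics checks use 0.5 nm/px where rasterisation detail
# matters. Particle separation is kept at 33 nm (2.6 x radius) so background
# annuli never graze a neighbour.

bench_model <- function() capsid_model()

bench_sim_config <- function(n_particles, p_full, snr = 5, seed = 1,
                             image_size = 1024L, pixel_size_nm = 1,
                             noiseless = FALSE, fixed_counts = FALSE) {
  model <- bench_model()
  sim_config(image_size_px = rep(image_size, 2L),
             pixel_size_nm = pixel_size_nm,
             n_particles = n_particles, p_full = p_full,
             contrast_scale = 2,
             noise_sd = if (noiseless) 0 else noise_sd_for_snr(model, 2, snr),
             blur_sigma_px = if (noiseless) 0 else 1,
             min_separation_nm = 33, fixed_counts = fixed_counts,
             seed = seed)
}

# precision/recall of picks against ground truth; a pick matches when its
# centre lies within the true outer radius of an unmatched truth particle
match_picks <- function(picks, truth, pixel_size_nm = 1) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(picks))) {
    sel <- if ("image_id" %in% names(truth))
      which(truth$image_id == picks$image_id[i] & !used)
    else which(!used)
    if (!length(sel)) next
    d <- sqrt((truth$x_px[sel] - picks$x_px[i])^2 +
                (truth$y_px[sel] - picks$y_px[i])^2)
    j <- sel[which.min(d)]
    if (min(d) < truth$radius_nm[j] / pixel_size_nm) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  list(precision = if (nrow(picks)) tp / nrow(picks) else NA_real_,
       recall = tp / nrow(truth), tp = tp)
}

# adjusted Rand index, computed from the contingency table (independent of
# any clustering library)
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# mean silhouette width for a 2-class labelling of points (n x d), direct
# O(n^2) definition
silhouette_mean <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- mean(d[i, !own])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# classify simulated images from ground-truth picks (profiling +
# classification only, detection bypassed)
classify_from_truth <- function(set, pixel_size_nm = 1,
                                posterior_threshold = 0.99) {
  picks <- truth_to_picks(set$truth, pixel_size_nm)
  pset <- profile_particles(set$micrographs, picks)
  model <- fit_pca(pset)
  res <- cluster_and_label(pca_scores(model, pset), profile_summaries(pset),
                           posterior_threshold = posterior_threshold)
  list(labels = res$assignments$label, truth = set$truth$class, result = res)
}
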