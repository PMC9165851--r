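# round half away from zero (printed tables use commercial rounding,
# not banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of full particles with a Wilson confidence interval
#'
#' The headline statistic: `100 * full / (full + empty)`. Uncertain and
#' excluded particles are reported but by default kept out of the
#' denominator — the classification is binary and ambiguous particles are
#' set aside. The 95% interval on the full fraction is the Wilson score
#' interval, chosen over the Wald interval for its behaviour near 0% and
#' 100% (reference-empty preparations sit near 1% full).
#'
#' @param full,empty,uncertain,excluded Class counts.
#' @param conf_level Confidence level of the Wilson interval.
#' @param rounding `"1dp"` (default) or `"integer"`, half-up.
#' @param uncertain_in_denominator Count uncertain particles in the
#'   denominator.
#' @param n_images Number of micrographs contributing (provenance).
#' @param seed Seed recorded for provenance.
#' @return Object of class `quant_report`: `counts`, `percent_full` (rounded
#'   per rule), `percent_full_raw`, `ci_95` (percent), `denominator`,
#'   `rounding`, `n_images`, `seed`.
#' @examples
#' percent_full(full = 750, empty = 750)
#' @export
percent_full <- function(full, empty, uncertain = 0L, excluded = 0L,
                         conf_level = 0.95, rounding = c("1dp", "integer"),
                         uncertain_in_denominator = FALSE,
                         n_images = NA_integer_, seed = NA_integer_) {
  rounding <- match.arg(rounding)
  stopifnot(full >= 0, empty >= 0, uncertain >= 0, excluded >= 0)
  denom <- full + empty + if (uncertain_in_denominator) uncertain else 0L
  if (denom <= 0) stop("no classified particles: full + empty must be > 0")
  p_raw <- 100 * full / denom
  ci <- suppressWarnings(
    stats::prop.test(full, denom, conf.level = conf_level,
                     correct = FALSE)$conf.int) * 100
  digits <- if (rounding == "1dp") 1L else 0L
  structure(list(counts = c(full = full, empty = empty,
                            uncertain = uncertain, excluded = excluded),
                 percent_full = round_half_up(p_raw, digits),
                 percent_full_raw = p_raw,
                 ci_95 = as.numeric(ci), denominator = denom,
                 conf_level = conf_level, rounding = rounding,
                 n_images = n_images, seed = seed),
            class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf(
    "<quant_report> %%full = %s (%d/%d classified; %d uncertain, %d excluded)\n",
    format(x$percent_full), x$counts[["full"]], x$denominator,
    x$counts[["uncertain"]], x$counts[["excluded"]]))
  cat(sprintf("  %d%% CI [%.2f, %.2f]%%", round(100 * x$conf_level),
              x$ci_95[1], x$ci_95[2]))
  if (!is.na(x$n_images)) cat(" from", x$n_images, "image(s)")
  cat("\n")
  invisible(x)
}

#' Run the full estimation pipeline on a set of micrographs
#'
#' detect -> refine/profile -> PCA -> mixture classification -> percent
#' full. The minimum counting rule (at least `config$min_images` images and
#' `config$min_particles` curated particles) is checked first; failures stop
#' unless `allow_short = TRUE`, which downgrades the stop to a warning.
#'
#' @param micrographs List of [micrograph()] objects (one sample).
#' @param config A [run_config()].
#' @param picks Optional pre-curated pick table; when NULL, picks are
#'   detected from scratch.
#' @param allow_short Proceed (with a warning) when the counting rule fails.
#' @return A `quant_report` with attributes `classification`
#'   (the `classification_result`) and `picks` (the pick table used).
#' @export
estimate_from_pipeline <- function(micrographs, config = run_config(),
                                   picks = NULL, allow_short = FALSE) {
  if (inherits(micrographs, "micrograph")) micrographs <- list(micrographs)
  stopifnot(inherits(config, "run_config"))
  if (is.null(picks)) {
    pick_list <- lapply(seq_along(micrographs), function(k)
      detect_particles(micrographs[[k]], config, image_id = k))
    picks <- do.call(rbind, pick_list)
  }
  gate <- enforce_minimum_count(picks, config$min_particles, config$min_images)
  if (!gate$pass) {
    msg <- sprintf(
      "minimum counting rule not met: %d image(s), %d particle(s), shortfall %d",
      gate$n_images, gate$n_picks, gate$shortfall)
    if (allow_short) warning(msg) else stop(msg)
  }
  pset <- profile_particles(micrographs, picks, bins = config$profile_bins)
  model <- fit_pca(pset)
  scores <- pca_scores(model, pset)
  res <- cluster_and_label(scores, profile_summaries(pset),
                           particle_id = seq_len(nrow(pset$meta)),
                           posterior_threshold = config$posterior_threshold)
  tab <- table(factor(res$assignments$label,
                      levels = c("full", "empty", "uncertain", "excluded")))
  n_excluded_curation <- nrow(picks) - nrow(analysis_picks(picks))
  report <- percent_full(full = tab[["full"]], empty = tab[["empty"]],
                         uncertain = tab[["uncertain"]],
                         excluded = tab[["excluded"]] + n_excluded_curation,
                         rounding = config$rounding,
                         uncertain_in_denominator =
                           config$uncertain_in_denominator,
                         n_images = length(micrographs), seed = config$seed)
  attr(report, "classification") <- res
  attr(report, "picks") <- picks
  report
}

#' Monte-Carlo study of the particle count needed for a stable estimate
#'
#' For every combination of sample size `n` and true full fraction `p`,
#' draws `replicates` binomial counts and reports the standard deviation of
#' the estimated percent-full, alongside the closed form
#' `100 * sqrt(p (1 - p) / n)`. This is the design calculation behind
#' counting at least 1500 particles per sample: at p = 0.5 the sampling sd
#' is then about 1.3 percentage points.
#'
#' @param n_grid Sample sizes.
#' @param p_grid True full fractions in `[0, 1]`.
#' @param replicates Monte-Carlo replicates per cell (>= 100).
#' @param seed Integer seed.
#' @return Object of class `sample_size_curve`: data.frame `n, p, sd_mc,
#'   sd_closed` plus `replicates`/`seed` attributes.
#' @export
sample_size_study <- function(n_grid = c(100, 500, 1500, 6000),
                              p_grid = c(0.05, 0.25, 0.5, 0.8),
                              replicates = 1000L, seed = 1L) {
  stopifnot(replicates >= 100, all(n_grid >= 1),
            all(p_grid >= 0), all(p_grid <= 1))
  grid <- expand.grid(n = as.integer(n_grid), p = p_grid)
  withr::with_seed(seed, {
    grid$sd_mc <- vapply(seq_len(nrow(grid)), function(i) {
      stats::sd(100 * stats::rbinom(replicates, grid$n[i], grid$p[i]) /
                  grid$n[i])
    }, numeric(1))
  })
  grid$sd_closed <- 100 * sqrt(grid$p * (1 - grid$p) / grid$n)
  structure(grid, class = c("sample_size_curve", "data.frame"),
            replicates = replicates, seed = seed)
}
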