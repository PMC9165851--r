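#' Geometric capsid model
#'
#' Describes an idealised icosahedral capsid as a spherical protein shell,
#' optionally containing packaged genome, for projection into a 2-D
#' bright-field TEM image. An empty capsid is the shell alone; a full capsid
#' additionally projects its interior at a relative density
#' `interior_density_rel` (genome + associated material vs shell protein).
#'
#' @param outer_radius_nm Outer shell radius in nm. The default 12.5 nm gives
#'   a 25 nm particle, in the middle of the 18--28 nm detection window used
#'   for AAV capsids in cryoTEM.
#' @param shell_thickness_nm Protein shell thickness in nm.
#' @param interior_density_rel Relative density of the capsid interior
#'   (0 = empty lumen; ~0.8 approximates a packaged single-stranded genome).
#' @return An object of class `capsid_model`.
#' @examples
#' m <- capsid_model()
#' projected_thickness(c(0, 10, 12.5), m, "empty")
#' @export
capsid_model <- function(outer_radius_nm = 12.5, shell_thickness_nm = 2.5,
                         interior_density_rel = 0.8) {
  stopifnot(is.numeric(outer_radius_nm), length(outer_radius_nm) == 1L,
            is.numeric(shell_thickness_nm), length(shell_thickness_nm) == 1L,
            is.numeric(interior_density_rel), length(interior_density_rel) == 1L)
  if (!(shell_thickness_nm > 0 && shell_thickness_nm < outer_radius_nm))
    stop("shell_thickness_nm must lie in (0, outer_radius_nm)")
  if (interior_density_rel < 0)
    stop("interior_density_rel must be >= 0")
  structure(list(outer_radius_nm = outer_radius_nm,
                 shell_thickness_nm = shell_thickness_nm,
                 interior_density_rel = interior_density_rel),
            class = "capsid_model")
}

# chord length through a sphere of radius R at impact parameter r (nm)
.chord <- function(R, r) 2 * sqrt(pmax(R^2 - r^2, 0))

#' Projected mass-thickness of a capsid
#'
#' Line integral of relative density along the beam through a spherical-shell
#' capsid at radial distance `r` from its centre, in nm-equivalents of shell
#' protein. An empty capsid projects the shell chord difference
#' \eqn{2(\sqrt{R_o^2-r^2} - \sqrt{R_i^2-r^2})}; a full capsid adds the
#' interior chord weighted by `interior_density_rel`. The empty profile is
#' maximal at the inner radius \eqn{R_i} (the dark ring seen in micrographs),
#' the full profile at the centre.
#'
#' @param r Radial distances in nm (vectorised, non-negative).
#' @param model A [capsid_model()].
#' @param cls `"full"` or `"empty"`.
#' @return Numeric vector of projected thickness (nm-equivalent), 0 beyond
#'   the outer radius.
#' @export
projected_thickness <- function(r, model, cls = c("full", "empty")) {
  cls <- match.arg(cls)
  stopifnot(inherits(model, "capsid_model"), all(r >= 0))
  R_o <- model$outer_radius_nm
  R_i <- R_o - model$shell_thickness_nm
  shell <- .chord(R_o, r) - .chord(R_i, r)
  if (cls == "empty") shell
  else shell + model$interior_density_rel * .chord(R_i, r)
}

#' Simulation configuration
#'
#' Imaging and sampling parameters for [simulate_micrograph()]. Defaults
#' mirror a 2048 x 2048 CCD at 0.5 nm/px; benchmarks in this package use
#' smaller frames at 1 nm/px for throughput.
#'
#' @param image_size_px Integer pair (rows, cols).
#' @param pixel_size_nm Physical pixel size, nm per pixel.
#' @param n_particles Number of capsids to place.
#' @param p_full Probability a particle is full (classes are drawn
#'   i.i.d. Bernoulli unless `fixed_counts = TRUE`, in which case exactly
#'   `round(p_full * n_particles)` particles are full).
#' @param contrast_scale Intensity decrement per nm-equivalent of projected
#'   density (particles are darker than background: bright-field convention).
#' @param background_level Mean background intensity.
#' @param noise_sd Standard deviation of additive zero-mean Gaussian noise.
#' @param noise_model `"gaussian"` (default) or `"poisson"` (shot noise with
#'   variance equal to the local mean scaled so the background sd equals
#'   `noise_sd`).
#' @param blur_sigma_px Gaussian blur applied after rasterisation (a simple
#'   stand-in for defocus; 0 disables).
#' @param min_separation_nm Minimum centre-to-centre distance between
#'   particles; must be at least one particle diameter.
#' @param fixed_counts Draw exactly `round(p_full * n_particles)` full
#'   particles instead of Bernoulli sampling.
#' @param seed Integer seed; the same seed reproduces the image bit for bit.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(image_size_px = c(2048L, 2048L), pixel_size_nm = 0.5,
                       n_particles = 100L, p_full = 0.5,
                       contrast_scale = 2, background_level = 100,
                       noise_sd = 0, noise_model = c("gaussian", "poisson"),
                       blur_sigma_px = 0, min_separation_nm = 25,
                       fixed_counts = FALSE, seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 16),
            pixel_size_nm > 0, n_particles >= 0,
            p_full >= 0, p_full <= 1, contrast_scale > 0, noise_sd >= 0,
            blur_sigma_px >= 0, min_separation_nm > 0)
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_nm = pixel_size_nm,
                 n_particles = as.integer(n_particles), p_full = p_full,
                 contrast_scale = contrast_scale,
                 background_level = background_level,
                 noise_sd = noise_sd, noise_model = noise_model,
                 blur_sigma_px = blur_sigma_px,
                 min_separation_nm = min_separation_nm,
                 fixed_counts = isTRUE(fixed_counts), seed = seed),
            class = "sim_config")
}

#' Noise level for a target signal-to-noise ratio
#'
#' SNR here is the peak depth of a full particle (contrast_scale times the
#' central projected thickness) divided by the pixel noise sd.
#'
#' @param model A [capsid_model()].
#' @param contrast_scale Intensity per nm-equivalent.
#' @param snr Target ratio.
#' @return Noise sd in intensity units.
#' @export
noise_sd_for_snr <- function(model, contrast_scale, snr) {
  stopifnot(snr > 0)
  contrast_scale * projected_thickness(0, model, "full") / snr
}

# Dart-throwing placement with a minimum separation; 0-based pixel coords.
.place_particles <- function(n, size_px, min_sep_px, margin_px) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  lo_x <- margin_px; hi_x <- size_px[2] - 1 - margin_px
  lo_y <- margin_px; hi_y <- size_px[1] - 1 - margin_px
  if (hi_x <= lo_x || hi_y <= lo_y)
    stop("image too small for particle margin of ", round(margin_px, 1), " px")
  xs <- numeric(n); ys <- numeric(n); placed <- 0L
  max_attempts <- 400L * n
  for (a in seq_len(max_attempts)) {
    x <- stats::runif(1, lo_x, hi_x); y <- stats::runif(1, lo_y, hi_y)
    if (placed == 0L ||
        all((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2 >=
              min_sep_px^2)) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
      if (placed == n) break
    }
  }
  if (placed < n)
    stop("could not place ", n, " particles at min separation ",
         round(min_sep_px, 1), " px in a ", size_px[1], "x", size_px[2],
         " px image (placed ", placed, ")")
  cbind(x = xs, y = ys)
}

# Render one particle into `img` (matrix [row, col], 0-based centre x/y),
# subtracting contrast * projected thickness, 4x4 super-sampled per pixel.
.render_particle <- function(img, xc, yc, model, cls, pixel_size_nm,
                             contrast_scale) {
  R_px <- model$outer_radius_nm / pixel_size_nm
  hw <- ceiling(R_px) + 1L
  rows <- max(1L, floor(yc + 1 - hw)):min(nrow(img), ceiling(yc + 1 + hw))
  cols <- max(1L, floor(xc + 1 - hw)):min(ncol(img), ceiling(xc + 1 + hw))
  offs <- (seq_len(4) - 2.5) / 4           # -0.375 -0.125 0.125 0.375
  dy0 <- (rows - 1) - yc
  dx0 <- (cols - 1) - xc
  acc <- matrix(0, length(rows), length(cols))
  for (oy in offs) {
    dy2 <- (dy0 + oy)^2
    for (ox in offs) {
      dx2 <- (dx0 + ox)^2
      r_nm <- sqrt(outer(dy2, dx2, `+`)) * pixel_size_nm
      acc <- acc + projected_thickness(r_nm, model, cls)
    }
  }
  img[rows, cols] <- img[rows, cols] - contrast_scale * acc / 16
  img
}

#' Simulate a cryoTEM micrograph of mixed full and empty capsids
#'
#' Places non-overlapping capsids at random positions, draws each particle's
#' class (full/empty) with probability `p_full`, rasterises the analytic
#' projected thickness by 4 x 4 super-sampling, optionally blurs, and adds
#' noise. Particles are darker than the background. The returned ground
#' truth records each particle's centre (0-based pixel coordinates,
#' x = column, y = row), class and radius.
#'
#' @param cfg A [sim_config()].
#' @param model A [capsid_model()].
#' @return A list with elements `micrograph` (a [micrograph()]) and `truth`
#'   (data.frame `particle_id, x_px, y_px, radius_nm, class`).
#' @examples
#' sim <- simulate_micrograph(
#'   sim_config(image_size_px = c(256, 256), pixel_size_nm = 1,
#'              n_particles = 5, p_full = 0.5, seed = 1),
#'   capsid_model())
#' table(sim$truth$class)
#' @export
simulate_micrograph <- function(cfg, model = capsid_model()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(model, "capsid_model"))
  if (cfg$min_separation_nm < 2 * model$outer_radius_nm)
    stop("min_separation_nm must be >= one particle diameter (",
         2 * model$outer_radius_nm, " nm)")
  run <- function() .simulate_micrograph_impl(cfg, model)
  if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, run()) else run()
}

.simulate_micrograph_impl <- function(cfg, model) {
  n <- cfg$n_particles
  px <- cfg$pixel_size_nm
  R_px <- model$outer_radius_nm / px
  # margin keeps the background annulus (1.6 r) inside the frame
  centres <- .place_particles(n, cfg$image_size_px,
                              cfg$min_separation_nm / px, 1.7 * R_px)
  if (n > 0L) {
    if (cfg$fixed_counts) {
      n_full <- round(cfg$p_full * n)
      cls <- sample(rep(c("full", "empty"), c(n_full, n - n_full)))
    } else {
      cls <- ifelse(stats::runif(n) < cfg$p_full, "full", "empty")
    }
  } else cls <- character(0)

  img <- matrix(cfg$background_level, cfg$image_size_px[1], cfg$image_size_px[2])
  for (i in seq_len(n))
    img <- .render_particle(img, centres[i, "x"], centres[i, "y"], model,
                            cls[i], px, cfg$contrast_scale)
  if (cfg$blur_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = cfg$blur_sigma_px))
  if (cfg$noise_sd > 0) {
    if (cfg$noise_model == "gaussian") {
      img <- img + stats::rnorm(length(img), sd = cfg$noise_sd)
    } else {
      # shot noise: variance proportional to local mean, scaled so the
      # background pixel sd equals noise_sd
      dose <- cfg$background_level / cfg$noise_sd^2
      img <- stats::rpois(length(img), pmax(img, 0) * dose) / dose
      dim(img) <- cfg$image_size_px
    }
  }
  truth <- data.frame(particle_id = seq_len(n),
                      x_px = if (n) centres[, "x"] else numeric(0),
                      y_px = if (n) centres[, "y"] else numeric(0),
                      radius_nm = rep(model$outer_radius_nm, n),
                      class = cls, stringsAsFactors = FALSE)
  list(micrograph = micrograph(img, pixel_size_nm = px, modality = "cryo",
                               source_path = "<simulated>"),
       truth = truth)
}

#' Convert simulation ground truth to a pick table
#'
#' Builds a pick table in the [read_particle_table()] schema from a ground
#' truth data.frame, for running the profiling/classification stages on
#' known centres (isolating them from detection in simulation studies).
#'
#' @param truth Ground truth from [simulate_micrograph()] or
#'   [simulate_image_set()].
#' @param pixel_size_nm Pixel size used to convert radii to px.
#' @return Pick data.frame with `status = "auto"`, `label = "unassigned"`.
#' @export
truth_to_picks <- function(truth, pixel_size_nm) {
  data.frame(particle_id = seq_len(nrow(truth)),
             image_id = if ("image_id" %in% names(truth)) truth$image_id else 1L,
             x_px = truth$x_px, y_px = truth$y_px,
             radius_px = truth$radius_nm / pixel_size_nm,
             score = NA_real_, status = "auto", label = "unassigned",
             stringsAsFactors = FALSE)
}

#' Simulate a replicate set of micrographs
#'
#' Convenience wrapper generating `n_images` independent micrographs from one
#' configuration, with per-image seeds derived from `cfg$seed`.
#'
#' @param cfg A [sim_config()]; `cfg$seed` must be set.
#' @param model A [capsid_model()].
#' @param n_images Number of micrographs.
#' @return List with `micrographs` (list of [micrograph()]) and `truth`
#'   (row-bound ground truth with an `image_id` column).
#' @export
simulate_image_set <- function(cfg, model = capsid_model(), n_images = 3L) {
  stopifnot(n_images >= 1, !is.null(cfg$seed))
  mics <- vector("list", n_images)
  truths <- vector("list", n_images)
  for (k in seq_len(n_images)) {
    cfg_k <- cfg
    cfg_k$seed <- (cfg$seed * 1009L + k) %% .Machine$integer.max
    sim <- simulate_micrograph(cfg_k, model)
    sim$truth$image_id <- k
    mics[[k]] <- sim$micrograph
    truths[[k]] <- sim$truth
  }
  list(micrographs = mics, truth = do.call(rbind, truths))
}
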