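#' Gradient magnitude of a micrograph
#'
#' Per-pixel Euclidean norm of the two first-order central differences,
#' after optional Gaussian smoothing. Capsid rims produce ring-shaped maxima
#' at roughly the outer radius, which the circular Hough stage accumulates.
#'
#' @param m A [micrograph()] or numeric matrix.
#' @param smooth_sigma_px Gaussian smoothing sd in px (0 = none).
#' @return Non-negative numeric matrix of the same size.
#' @export
gradient_magnitude <- function(m, smooth_sigma_px = 0) {
  g <- .gradients(m, smooth_sigma_px)
  sqrt(g$gx^2 + g$gy^2)
}

.gradients <- function(m, smooth_sigma_px = 0) {
  img <- if (inherits(m, "micrograph")) m$intensities else m
  stopifnot(is.matrix(img))
  if (smooth_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = smooth_sigma_px))
  nr <- nrow(img); nc <- ncol(img)
  # central differences with replicated edges
  gy <- (img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]) / 2
  gx <- (img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]) / 2
  list(gx = gx, gy = gy)
}

# ring kernels of radius r px (width 1 px) weighted by the outward radial
# unit vector; convolving gx/gy with these accumulates the signed radial
# gradient component on the circle (capsid rims, dark inside, point outward)
.ring_kernels <- function(r) {
  hw <- ceiling(r) + 1L
  ax <- (-hw):hw
  dy <- matrix(ax, length(ax), length(ax))       # rows = y offset
  dx <- t(dy)
  d <- sqrt(dx^2 + dy^2)
  on <- d > r - 0.5 & d <= r + 0.5
  n <- sum(on)
  u <- ifelse(on & d > 0, 1 / pmax(d, 1e-9), 0)
  # filter2 performs convolution (kernel reflected), so the kernels carry the
  # negated offsets to realise the correlation with the outward unit vector
  list(kx = -dx * u / n, ky = -dy * u / n, n = n)
}

# 3x3 local maxima of a matrix (strictly greater than all 8 neighbours)
.local_maxima <- function(a) {
  nr <- nrow(a); nc <- ncol(a)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- a
  res <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    res <- res & (a > pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)])
  }
  res
}

#' Detect capsid-sized particles
#'
#' Circular Hough accumulation on the gradient-magnitude image over the
#' radii spanned by the physical diameter window: for each candidate radius,
#' the mean gradient on the circle is computed by ring convolution; the
#' per-pixel maximum over radii forms the score map. Scores are expressed
#' relative to the image's robust background gradient level (median), so the
#' threshold is dimensionless and transfers across contrast settings. Local
#' maxima above threshold are kept, then greedily non-maximum suppressed
#' (stronger score wins; ties by lower y then lower x); picks whose centre is
#' closer than `1.2 * radius` to the border are discarded, as their radial
#' profile would be truncated.
#'
#' @param m A [micrograph()].
#' @param config A [run_config()] carrying the size window, smoothing,
#'   threshold, NMS overlap and eccentricity settings.
#' @param image_id Identifier stored in the `image_id` column.
#' @return Pick data.frame in the [read_particle_table()] schema, with an
#'   `eccentricity` attribute column when refinement is enabled.
#' @export
detect_particles <- function(m, config = run_config(), image_id = 1L) {
  stopifnot(inherits(m, "micrograph"), inherits(config, "run_config"))
  px <- m$pixel_size_nm
  r_min_px <- config$min_diameter_nm / 2 / px
  r_max_px <- config$max_diameter_nm / 2 / px
  if (config$min_diameter_nm / px < 4)
    stop("size window below pixel resolution: min diameter must span >= 4 px")
  g <- .gradients(m, config$smooth_sigma_px)
  grad <- sqrt(g$gx^2 + g$gy^2)
  noise_level <- stats::median(grad)
  if (noise_level <= 0) noise_level <- mean(grad) + .Machine$double.eps

  radii <- seq(ceiling(r_min_px), floor(r_max_px), by = 1)
  if (!length(radii)) radii <- (r_min_px + r_max_px) / 2
  # probe radii just outside the window: a candidate whose response is still
  # rising at the window edge is a larger (or smaller) object whose rim the
  # in-window circles merely osculate, and is rejected below
  probe_lo <- min(radii) - 1
  probe_hi <- max(radii) + 1
  radii_all <- c(probe_lo, radii, probe_hi)
  score_map <- matrix(-Inf, nrow(grad), ncol(grad))
  radius_map <- matrix(radii[1], nrow(grad), ncol(grad))
  for (r in radii_all) {
    k <- .ring_kernels(r)
    acc <- as.matrix(EBImage::filter2(g$gx, k$kx, boundary = 0)) +
      as.matrix(EBImage::filter2(g$gy, k$ky, boundary = 0))
    upd <- acc > score_map
    score_map[upd] <- acc[upd]
    radius_map[upd] <- r
  }
  score_map <- score_map / noise_level

  cand <- which(.local_maxima(score_map) & score_map >= config$detect_threshold &
                  radius_map > probe_lo & radius_map < probe_hi,
                arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(.empty_picks())
  df <- data.frame(y_px = cand[, 1] - 1, x_px = cand[, 2] - 1,
                   radius_px = radius_map[cand],
                   score = score_map[cand])
  # deterministic order: score desc, then y asc, then x asc
  df <- df[order(-df$score, df$y_px, df$x_px), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i < nrow(df)) {
      j <- (i + 1):nrow(df)
      d <- sqrt((df$x_px[j] - df$x_px[i])^2 + (df$y_px[j] - df$y_px[i])^2)
      keep[j][d < config$nms_overlap * (df$radius_px[j] + df$radius_px[i])] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]

  # border rule: full profiling neighbourhood must fit
  nr <- nrow(m$intensities); nc <- ncol(m$intensities)
  b <- 1.2 * df$radius_px
  df <- df[df$x_px >= b & df$x_px <= nc - 1 - b &
             df$y_px >= b & df$y_px <= nr - 1 - b, , drop = FALSE]

  ecc <- rep(NA_real_, nrow(df))
  if (config$refine_ellipse && nrow(df)) {
    for (i in seq_len(nrow(df)))
      ecc[i] <- .pick_eccentricity(m, df$x_px[i], df$y_px[i], df$radius_px[i])
    sel <- is.na(ecc) | ecc <= config$ecc_max
    df <- df[sel, , drop = FALSE]; ecc <- ecc[sel]
  }

  # size window check on the final radii
  dia_nm <- 2 * df$radius_px * px
  sel <- dia_nm >= config$min_diameter_nm & dia_nm <= config$max_diameter_nm
  df <- df[sel, , drop = FALSE]; ecc <- ecc[sel]
  if (!nrow(df)) return(.empty_picks())

  out <- data.frame(particle_id = seq_len(nrow(df)), image_id = image_id,
                    x_px = df$x_px, y_px = df$y_px, radius_px = df$radius_px,
                    score = df$score, status = "auto", label = "unassigned",
                    stringsAsFactors = FALSE)
  attr(out, "eccentricity") <- ecc
  rownames(out) <- NULL
  out
}

.empty_picks <- function() {
  data.frame(particle_id = integer(0), image_id = integer(0),
             x_px = numeric(0), y_px = numeric(0), radius_px = numeric(0),
             score = numeric(0), status = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

# moment-based eccentricity of the darkness blob around a pick
.pick_eccentricity <- function(m, xc, yc, r_px) {
  img <- m$intensities
  hw <- ceiling(1.2 * r_px)
  rows <- max(1L, round(yc + 1 - hw)):min(nrow(img), round(yc + 1 + hw))
  cols <- max(1L, round(xc + 1 - hw)):min(ncol(img), round(xc + 1 + hw))
  patch <- img[rows, cols]
  w <- pmax(mean(patch) - patch, 0)
  if (sum(w) <= 0) return(NA_real_)
  ys <- (rows - 1) - yc; xs <- (cols - 1) - xc
  W <- sum(w)
  my <- sum(w * ys) / W; mx <- sum(t(w) * xs) / W
  cyy <- sum(w * (ys - my)^2) / W
  cxx <- sum(t(w) * (xs - mx)^2) / W
  cxy <- sum(w * outer(ys - my, xs - mx)) / W
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[1] <= 0) return(NA_real_)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

#' Enforce the minimum counting rule
#'
#' A sample's dataset passes when it contains at least `min_images`
#' micrographs and at least `min_particles` curated particles (default 1500,
#' the size at which the binomial sampling sd of the percent-full estimate
#' drops to about 1.3 percentage points at p = 0.5; see
#' [sample_size_study()]).
#'
#' @param picks Pick data.frame (all images of one sample).
#' @param min_particles Minimum curated particle count.
#' @param min_images Minimum number of distinct images.
#' @return List with `pass`, `n_images`, `n_picks`, and `shortfall` (particles
#'   still missing; 0 when the count satisfies the rule).
#' @export
enforce_minimum_count <- function(picks, min_particles = 1500L,
                                  min_images = 3L) {
  kept <- analysis_picks(picks)
  n_images <- length(unique(kept$image_id))
  n_picks <- nrow(kept)
  list(pass = n_images >= min_images && n_picks >= min_particles,
       n_images = n_images, n_picks = n_picks,
       shortfall = max(0L, min_particles - n_picks))
}
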