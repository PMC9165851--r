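#' Refine a particle centre
#'
#' Iterated intensity-weighted centroid of (background - image) within
#' 1.2 x the pick radius: darker-than-background mass pulls the centre onto
#' the particle. Stops after at most 5 iterations or when the update falls
#' below 0.1 px. If the accumulated shift would exceed half the pick radius,
#' or the neighbourhood carries no darkness mass (flat background), the
#' original centre is kept and the result is flagged.
#'
#' @param m A [micrograph()].
#' @param x_px,y_px Initial centre, 0-based pixel coordinates.
#' @param radius_px Pick radius in px.
#' @return List `x_px`, `y_px`, `shift_px` (total displacement), `flagged`.
#' @export
refine_centre <- function(m, x_px, y_px, radius_px) {
  stopifnot(inherits(m, "micrograph"))
  img <- m$intensities
  x0 <- x_px; y0 <- y_px
  r_in <- 1.2 * radius_px
  for (it in seq_len(5)) {
    hw <- ceiling(r_in) + 1L
    rows <- max(1L, round(y_px + 1 - hw)):min(nrow(img), round(y_px + 1 + hw))
    cols <- max(1L, round(x_px + 1 - hw)):min(ncol(img), round(x_px + 1 + hw))
    patch <- img[rows, cols]
    ys <- (rows - 1) - y_px; xs <- (cols - 1) - x_px
    d2 <- outer(ys^2, xs^2, `+`)
    bg <- mean(patch[d2 > (1.3 * radius_px)^2])
    if (!is.finite(bg)) bg <- mean(patch)
    w <- pmax(bg - patch, 0)
    w[d2 > r_in^2] <- 0
    W <- sum(w)
    if (W <= .Machine$double.eps * length(w))
      return(list(x_px = x0, y_px = y0, shift_px = 0, flagged = TRUE))
    dy <- sum(w * ys) / W
    dx <- sum(t(w) * xs) / W
    x_new <- x_px + dx; y_new <- y_px + dy
    if (sqrt((x_new - x0)^2 + (y_new - y0)^2) > radius_px / 2)
      return(list(x_px = x0, y_px = y0, shift_px = 0, flagged = TRUE))
    x_px <- x_new; y_px <- y_new
    if (sqrt(dx^2 + dy^2) < 0.1) break
  }
  list(x_px = x_px, y_px = y_px,
       shift_px = sqrt((x_px - x0)^2 + (y_px - y0)^2), flagged = FALSE)
}

#' Radial density profile of one particle
#'
#' Mean intensity as a function of radial distance from the (refined)
#' particle centre, background-normalised and resampled to a fixed length.
#' Pixels out to `r_max = 1.2 * radius_px` are binned into native annuli of
#' width `max(1 px, r_max / bins)` (every native annulus holds at least one
#' pixel); native means are then linearly resampled to `bins` equal-width
#' bins over `[0, r_max]`. The background mean and sd are estimated from the
#' annulus `[1.3, 1.6] * radius_px` and the profile reported as
#' `(annulus mean - bg mean) / bg sd`. A full capsid is most negative at the
#' centre, an empty capsid at its inner shell radius. Normalising the radial
#' axis to each particle's own radius makes profiles of different-sized
#' capsids commensurate for PCA.
#'
#' @param m A [micrograph()].
#' @param x_px,y_px Particle centre (0-based; refine first).
#' @param radius_px Particle radius in px.
#' @param bins Profile length B.
#' @return List of class `radial_profile`: `values` (length `bins`),
#'   `r_max_px`, `bg_mean`, `bg_sd`, `bg_sd_degenerate` (TRUE when the
#'   background sd was below tolerance and a unit divisor was used).
#' @export
radial_profile <- function(m, x_px, y_px, radius_px, bins = 32L) {
  stopifnot(inherits(m, "micrograph"), radius_px > 0, bins >= 8)
  img <- m$intensities
  r_max <- 1.2 * radius_px
  r_bg <- 1.6 * radius_px
  if (x_px < r_max || y_px < r_max ||
      x_px > ncol(img) - 1 - r_max || y_px > nrow(img) - 1 - r_max)
    stop("particle centre closer than r_max to the image border")
  hw <- ceiling(r_bg) + 1L
  rows <- max(1L, round(y_px + 1 - hw)):min(nrow(img), round(y_px + 1 + hw))
  cols <- max(1L, round(x_px + 1 - hw)):min(ncol(img), round(x_px + 1 + hw))
  patch <- img[rows, cols]
  d <- sqrt(outer(((rows - 1) - y_px)^2, ((cols - 1) - x_px)^2, `+`))

  in_bg <- d >= 1.3 * radius_px & d <= r_bg
  if (sum(in_bg) < 8) stop("background annulus too small")
  # robust estimates: the annulus may graze a neighbouring particle at the
  # minimum allowed separation; median/MAD reject that minority of pixels
  bg_mean <- stats::median(patch[in_bg])
  bg_sd <- stats::mad(patch[in_bg])
  degenerate <- !is.finite(bg_sd) || bg_sd < 1e-9 * (abs(bg_mean) + 1)
  sd_used <- if (degenerate) 1 else bg_sd

  # bin at the target width when it spans at least ~one pixel (any annulus
  # of width >= 0.9 px contains a pixel centre); coarser particles fall back
  # to wider native annuli that are then resampled to `bins`
  width <- max(0.9, r_max / bins)
  n_native <- ceiling(r_max / width)
  idx <- pmin(floor(d / width) + 1L, n_native)
  sel <- d < r_max
  counts <- tabulate(idx[sel], nbins = n_native)
  if (any(counts == 0L))
    stop("empty radial annulus; particle too small for ", bins,
         " bins -- reduce bins or use a finer pixel size")
  sums <- as.vector(rowsum(patch[sel], idx[sel]))
  native <- sums / counts
  native_centres <- (seq_len(n_native) - 0.5) * width
  target_centres <- (seq_len(bins) - 0.5) * r_max / bins
  vals <- stats::approx(native_centres, native, xout = target_centres,
                        rule = 2)$y
  structure(list(values = (vals - bg_mean) / sd_used,
                 r_max_px = r_max, bg_mean = bg_mean, bg_sd = sd_used,
                 bg_sd_degenerate = degenerate),
            class = "radial_profile")
}

#' Radial profiles for a pick table
#'
#' Refines each pick's centre and computes its radial profile; picks whose
#' refined neighbourhood would cross the image border are dropped with a
#' message. Returns profiles as a matrix for PCA plus per-particle metadata.
#'
#' @param micrographs A [micrograph()] or list of micrographs, indexed by the
#'   picks' `image_id` (a single micrograph serves all ids).
#' @param picks Pick data.frame ([read_particle_table()] schema); only
#'   analysis rows are profiled (see [analysis_picks()]).
#' @param bins Profile length B.
#' @param refine Refine centres before profiling.
#' @return List of class `profile_set`: `profiles` (n x B matrix),
#'   `meta` (data.frame `particle_id, image_id, x_px, y_px, radius_px,
#'   r_max_px, bg_mean, bg_sd, refined_flag`), `bins`.
#' @export
profile_particles <- function(micrographs, picks, bins = 32L, refine = TRUE) {
  if (inherits(micrographs, "micrograph"))
    micrographs <- list(micrographs)
  kept <- analysis_picks(picks)
  ids <- unique(kept$image_id)
  prof <- matrix(NA_real_, nrow(kept), bins)
  meta <- kept[, c("particle_id", "image_id", "x_px", "y_px", "radius_px")]
  meta$r_max_px <- NA_real_; meta$bg_mean <- NA_real_; meta$bg_sd <- NA_real_
  meta$refined_flag <- FALSE
  ok <- rep(TRUE, nrow(kept))
  for (i in seq_len(nrow(kept))) {
    mic <- if (length(micrographs) == 1L) micrographs[[1L]]
           else micrographs[[match(kept$image_id[i], ids)]]
    x <- kept$x_px[i]; y <- kept$y_px[i]; r <- kept$radius_px[i]
    if (refine) {
      rc <- refine_centre(mic, x, y, r)
      x <- rc$x_px; y <- rc$y_px
      meta$refined_flag[i] <- rc$flagged
      meta$x_px[i] <- x; meta$y_px[i] <- y
    }
    rp <- tryCatch(radial_profile(mic, x, y, r, bins), error = function(e) e)
    if (inherits(rp, "error")) { ok[i] <- FALSE; next }
    prof[i, ] <- rp$values
    meta$r_max_px[i] <- rp$r_max_px
    meta$bg_mean[i] <- rp$bg_mean
    meta$bg_sd[i] <- rp$bg_sd
  }
  if (any(!ok))
    message(sum(!ok), " pick(s) dropped during profiling (border/annulus)")
  structure(list(profiles = prof[ok, , drop = FALSE],
                 meta = meta[ok, , drop = FALSE], bins = as.integer(bins)),
            class = "profile_set")
}

#' Write / read a profile CSV
#'
#' Schema `particle_id,image_id,b0..b<B-1>,r_max_px,bg_mean,bg_sd`.
#'
#' @param pset A `profile_set`.
#' @param path CSV path.
#' @return `path` (write) or a `profile_set` (read).
#' @export
write_profiles <- function(pset, path) {
  stopifnot(inherits(pset, "profile_set"))
  b <- pset$bins
  df <- cbind(pset$meta[, c("particle_id", "image_id")],
              as.data.frame(pset$profiles) |>
                stats::setNames(paste0("b", seq_len(b) - 1)),
              pset$meta[, c("r_max_px", "bg_mean", "bg_sd")])
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# coordinates: 0-based pixel centres; x = column, y = row", con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  meta <- df[, c("particle_id", "image_id", "r_max_px", "bg_mean", "bg_sd")]
  meta$x_px <- NA_real_; meta$y_px <- NA_real_; meta$radius_px <- NA_real_
  meta$refined_flag <- FALSE
  prof <- as.matrix(df[, bcols])
  dimnames(prof) <- NULL
  structure(list(profiles = prof, meta = meta, bins = length(bcols)),
            class = "profile_set")
}
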