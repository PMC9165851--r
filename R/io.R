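#' Micrograph container
#'
#' A 2-D intensity image with its physical pixel size. All pipeline
#' coordinates are 0-based pixel centres with x = column and y = row.
#'
#' @param intensities Numeric matrix (rows = y, cols = x), all finite.
#' @param pixel_size_nm Physical pixel size in nm/px, > 0.
#' @param modality `"cryo"` or `"nstem"`.
#' @param source_path Provenance string.
#' @return Object of class `micrograph`.
#' @export
micrograph <- function(intensities, pixel_size_nm, modality = c("cryo", "nstem"),
                       source_path = "<memory>") {
  modality <- match.arg(modality)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("intensities must be a numeric matrix (2-D data only)")
  if (!all(is.finite(intensities)))
    stop("intensities must all be finite")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be a single positive number")
  structure(list(intensities = intensities, pixel_size_nm = pixel_size_nm,
                 modality = modality, source_path = source_path),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %.4g nm/px, %s, source: %s\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_size_nm,
              x$modality, x$source_path))
  invisible(x)
}

# ---- MRC2014 (mode 2, 32-bit float) -----------------------------------------
# Minimal single-section MRC implementation: 1024-byte header, little-endian,
# x (column) fastest in the data block, voxel size stored via CELLA/MX.

#' Write a micrograph as MRC2014 (mode 2, float32)
#'
#' @param m A [micrograph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(m, path) {
  stopifnot(inherits(m, "micrograph"))
  img <- m$intensities
  nx <- ncol(img); ny <- nrow(img)
  con <- file(path, "wb"); on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(nx, ny, 1L))                      # NX NY NZ
  wi(2L)                                 # MODE 2 = float32
  wi(c(0L, 0L, 0L))                      # NXSTART..
  wi(c(nx, ny, 1L))                      # MX MY MZ
  wf(c(nx, ny, 1) * m$pixel_size_nm * 10) # CELLA in Angstrom
  wf(c(90, 90, 90))                      # CELLB
  wi(c(1L, 2L, 3L))                      # MAPC MAPR MAPS
  wf(c(min(img), max(img), mean(img)))   # DMIN DMAX DMEAN
  wi(0L); wi(0L)                         # ISPG NSYMBT
  wi(integer(25))                        # EXTRA (words 26-50)
  wf(c(0, 0, 0))                         # ORIGIN (words 50-52)
  writeBin(charToRaw("MAP "), con)       # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(img))                     # RMS
  wi(0L)                                 # NLABL
  writeBin(raw(800L), con)               # labels
  writeBin(as.numeric(t(img)), con, size = 4L, endian = "little")
  invisible(path)
}

.read_mrc <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  ri(3)                                  # nxstart
  mxyz <- ri(3)
  cella <- rf(3)
  rf(3); ri(3); rf(3); ri(1)
  nsymbt <- ri(1)
  if (dims[3] != 1L) stop("only single-section (2-D) MRC files are supported")
  if (mode != 2L) stop("only MRC mode 2 (float32) is supported, got mode ", mode)
  seek(con, 1024L + nsymbt)
  vals <- rf(dims[1] * dims[2])
  img <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  voxel_nm <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] / 10 else NA_real_
  list(intensities = img, pixel_size_nm = voxel_nm)
}

# ---- TIFF -------------------------------------------------------------------

#' Write a micrograph as 16-bit grayscale TIFF
#'
#' Intensities are linearly rescaled to the 16-bit range (the TIFF route is
#' for interoperability; use MRC for lossless round trips). TIFF stores no
#' physical pixel size, so reading back requires an override.
#'
#' @param m A [micrograph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(m, path) {
  stopifnot(inherits(m, "micrograph"))
  img <- m$intensities
  rng <- range(img)
  scl <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  tiff::writeTIFF(scl, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a micrograph from MRC2014 or TIFF
#'
#' Pixel size is taken from the MRC header voxel size when present, otherwise
#' from `pixel_size_nm`; an error is raised when neither is available.
#'
#' @param path Path to a `.mrc`/`.map` or `.tif`/`.tiff` file.
#' @param pixel_size_nm Optional override/fallback pixel size in nm/px.
#' @param modality `"cryo"` or `"nstem"`.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size_nm = NULL,
                            modality = c("cryo", "nstem")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "map")) {
    raw <- .read_mrc(path)
    px <- if (!is.null(pixel_size_nm)) pixel_size_nm else raw$pixel_size_nm
    if (is.na(px))
      stop("MRC header carries no voxel size and no pixel_size_nm override given")
    micrograph(raw$intensities, px, modality, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (is.null(pixel_size_nm))
      stop("TIFF files carry no pixel size; pass pixel_size_nm")
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
    if (length(dim(img)) != 2L) stop("non-2-D TIFF data")
    micrograph(img * 1.0, pixel_size_nm, modality, path)
  } else {
    stop("unknown micrograph format: .", ext, " (expected MRC or TIFF)")
  }
}

# ---- Particle tables --------------------------------------------------------

.pick_cols <- c("particle_id", "image_id", "x_px", "y_px", "radius_px",
                "score", "status", "label")
.pick_status_vocab <- c("auto", "added", "removed")
.pick_label_vocab <- c("unassigned", "full", "empty", "uncertain", "excluded")

.validate_picks <- function(picks) {
  missing <- setdiff(.pick_cols, names(picks))
  extra <- setdiff(names(picks), .pick_cols)
  if (length(missing) || length(extra))
    stop("particle table schema violation; missing: [",
         paste(missing, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]")
  bad_status <- setdiff(unique(picks$status), .pick_status_vocab)
  if (length(bad_status))
    stop("invalid status value(s): ", paste(bad_status, collapse = ", "))
  bad_label <- setdiff(unique(picks$label), .pick_label_vocab)
  if (length(bad_label))
    stop("invalid label value(s): ", paste(bad_label, collapse = ", "))
  picks[, .pick_cols]
}

#' Read / write a particle pick table
#'
#' CSV schema `particle_id,image_id,x_px,y_px,radius_px,score,status,label`
#' with `status` in auto/added/removed and `label` in
#' unassigned/full/empty/uncertain/excluded. Coordinates are 0-based pixel
#' centres (x = column, y = row), stated in a comment line at the top of each
#' file. Rows with `status = "removed"` are retained in files but excluded
#' from analysis sets (see [analysis_picks()]).
#'
#' @param path CSV path.
#' @return `read_particle_table`: a validated data.frame.
#' @export
read_particle_table <- function(path) {
  picks <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  .validate_picks(picks)
}

#' @rdname read_particle_table
#' @param picks Pick data.frame following the schema.
#' @return `write_particle_table`: `path`, invisibly.
#' @export
write_particle_table <- function(picks, path) {
  picks <- .validate_picks(picks)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# coordinates: 0-based pixel centres; x = column, y = row", con)
  utils::write.csv(picks, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Picks entering the analysis
#'
#' Drops curated-out rows: `status = "removed"` or `label = "excluded"`.
#'
#' @param picks Pick data.frame.
#' @return Filtered data.frame.
#' @export
analysis_picks <- function(picks) {
  picks <- .validate_picks(picks)
  picks[picks$status != "removed" & picks$label != "excluded", , drop = FALSE]
}

#' Apply a curation edit table to picks
#'
#' Curation is represented as status/label edits keyed by
#' `particle_id` + `image_id`: an edits table with columns
#' `particle_id,image_id,action[,x_px,y_px,radius_px,label]` where `action`
#' is `remove` (mark status removed), `exclude` (label excluded), `relabel`
#' (set `label`), or `add` (append a manual pick; requires coordinates).
#'
#' @param picks Pick data.frame.
#' @param edits Edit data.frame as above.
#' @return Curated pick data.frame.
#' @export
apply_curation <- function(picks, edits) {
  picks <- .validate_picks(picks)
  stopifnot(all(c("particle_id", "image_id", "action") %in% names(edits)))
  key <- function(d) paste(d$image_id, d$particle_id, sep = "\r")
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (e$action == "add") {
      stopifnot(all(c("x_px", "y_px", "radius_px") %in% names(edits)))
      picks <- rbind(picks, data.frame(
        particle_id = e$particle_id, image_id = e$image_id,
        x_px = e$x_px, y_px = e$y_px, radius_px = e$radius_px,
        score = NA_real_, status = "added",
        label = if ("label" %in% names(edits) && !is.na(e$label)) e$label
                else "unassigned"))
      next
    }
    hit <- key(picks) == paste(e$image_id, e$particle_id, sep = "\r")
    if (!any(hit)) stop("curation edit targets unknown particle: image ",
                        e$image_id, " id ", e$particle_id)
    if (e$action == "remove") picks$status[hit] <- "removed"
    else if (e$action == "exclude") picks$label[hit] <- "excluded"
    else if (e$action == "relabel") {
      if (!e$label %in% .pick_label_vocab) stop("invalid label: ", e$label)
      picks$label[hit] <- e$label
    } else stop("unknown curation action: ", e$action)
  }
  .validate_picks(picks)
}

# ---- Run configuration and run report ---------------------------------------

#' Pipeline run configuration
#'
#' Bundles the knobs shared across detection, profiling, classification and
#' quantification. The nsTEM modality widens the detection size window to
#' 25--35 nm (stain increases apparent particle size).
#'
#' @param modality `"cryo"` or `"nstem"`.
#' @param min_diameter_nm,max_diameter_nm Detection size window; defaults
#'   18--28 nm (cryo) or 25--35 nm (nsTEM).
#' @param profile_bins Radial profile length B.
#' @param posterior_threshold Mixture posterior below which a particle is
#'   labelled uncertain; in (0.5, 1).
#' @param min_particles Minimum curated particle count across images.
#' @param min_images Minimum number of micrographs per sample.
#' @param smooth_sigma_px Gaussian smoothing before the gradient.
#' @param detect_threshold Detector score threshold (ring-mean gradient over
#'   the image's robust gradient level; dimensionless).
#' @param nms_overlap Non-maximum suppression: suppress a weaker pick whose
#'   centre is closer than `nms_overlap * (r_i + r_j)` to a stronger one.
#' @param ecc_max Maximum eccentricity kept when ellipse refinement is on.
#' @param refine_ellipse Enable moment-based ellipse refinement.
#' @param rounding `"1dp"` or `"integer"` for reported percentages.
#' @param uncertain_in_denominator Count uncertain particles in the
#'   percent-full denominator (default FALSE: set aside).
#' @param seed Seed recorded in reports and used by stochastic stages.
#' @return Object of class `run_config`.
#' @export
run_config <- function(modality = c("cryo", "nstem"),
                       min_diameter_nm = NULL, max_diameter_nm = NULL,
                       profile_bins = 32L, posterior_threshold = 0.99,
                       min_particles = 1500L, min_images = 3L,
                       smooth_sigma_px = 2, detect_threshold = 2.0,
                       nms_overlap = 0.8, ecc_max = 0.4,
                       refine_ellipse = FALSE,
                       rounding = c("1dp", "integer"),
                       uncertain_in_denominator = FALSE, seed = 0L) {
  modality <- match.arg(modality)
  rounding <- match.arg(rounding)
  if (is.null(min_diameter_nm))
    min_diameter_nm <- if (modality == "cryo") 18 else 25
  if (is.null(max_diameter_nm))
    max_diameter_nm <- if (modality == "cryo") 28 else 35
  stopifnot(min_diameter_nm > 0, max_diameter_nm > min_diameter_nm,
            profile_bins >= 8, posterior_threshold > 0.5,
            posterior_threshold < 1, min_particles >= 1, min_images >= 1,
            detect_threshold > 0, nms_overlap > 0, ecc_max >= 0)
  structure(list(modality = modality, min_diameter_nm = min_diameter_nm,
                 max_diameter_nm = max_diameter_nm,
                 profile_bins = as.integer(profile_bins),
                 posterior_threshold = posterior_threshold,
                 min_particles = as.integer(min_particles),
                 min_images = as.integer(min_images),
                 smooth_sigma_px = smooth_sigma_px,
                 detect_threshold = detect_threshold,
                 nms_overlap = nms_overlap, ecc_max = ecc_max,
                 refine_ellipse = isTRUE(refine_ellipse),
                 rounding = rounding,
                 uncertain_in_denominator = isTRUE(uncertain_in_denominator),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a JSON run report
#'
#' Captures the configuration, seed, and MD5 hashes of the input files so a
#' deterministic stage can be re-run reproducibly from the report alone.
#'
#' @param path Output JSON path.
#' @param config A `run_config` (or any list).
#' @param inputs Character vector of input file paths (hashed).
#' @param results Optional list of stage results to embed.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(path, config, inputs = character(0),
                             results = NULL) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  report <- list(package = "capsidquant",
                 version = as.character(utils::packageVersion("capsidquant")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 config = unclass(config), input_md5 = hashes,
                 results = results)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
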