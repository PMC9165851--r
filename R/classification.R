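#' Fit a PCA model to radial profiles
#'
#' Mean-centred (not variance-scaled) principal component analysis of the
#' profile matrix; the first two components are retained — full and empty
#' capsids separate into two clusters in this plane because their profiles
#' differ most strongly in the central bins. Component signs are fixed so
#' the loading at the central bin (r = 0) is non-positive, making scores
#' reproducible across runs: darker centres (full particles) then score
#' higher on a component with negative central loading times the negative
#' central profile value.
#'
#' @param profiles Numeric matrix (particles x bins) or a `profile_set`.
#' @return Object of class `pca_model`: `center` (mean profile), `loadings`
#'   (bins x 2, orthonormal columns), `var_explained` (fractions for
#'   components 1 and 2), `sdev_all`.
#' @export
fit_pca <- function(profiles) {
  if (inherits(profiles, "profile_set")) profiles <- profiles$profiles
  stopifnot(is.matrix(profiles))
  if (nrow(profiles) < 10) stop("need at least 10 profiles for PCA")
  if (!all(is.finite(profiles))) stop("profiles contain non-finite values")
  total_var <- sum(apply(profiles, 2, stats::var))
  if (total_var <= .Machine$double.eps)
    stop("profiles have zero total variance; PCA undefined")
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  if (k < 2L)  # degenerate width-1 data cannot occur for B >= 8, be safe
    load <- cbind(load, 0)
  for (j in 1:2) if (load[1, j] > 0) load[, j] <- -load[, j]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(center = pc$center, loadings = load,
                 var_explained = c(ve, 0, 0)[1:2], sdev_all = pc$sdev),
            class = "pca_model")
}

#' Project profiles onto a fitted PCA model
#'
#' @param model A `pca_model`.
#' @param profiles Matrix (particles x bins) or `profile_set`.
#' @return n x 2 score matrix (columns `pc1`, `pc2`).
#' @export
pca_scores <- function(model, profiles) {
  if (inherits(profiles, "profile_set")) profiles <- profiles$profiles
  stopifnot(inherits(model, "pca_model"),
            ncol(profiles) == length(model$center))
  s <- sweep(profiles, 2, model$center) %*% model$loadings
  colnames(s) <- c("pc1", "pc2")
  s
}

#' Central and ring profile summaries
#'
#' Physical anchors for cluster labelling: `central` is the mean of the
#' profile bins inside 0.4 x the particle radius (where a packaged genome
#' shows up), `ring` the mean of the bins covering 0.6--1.0 x the radius
#' (around the shell's inner wall, where an empty capsid is darkest).
#'
#' @param profiles Matrix (particles x bins) or `profile_set`; bins span
#'   radius 0 to 1.2 x the particle radius.
#' @return data.frame with `central` and `ring` columns.
#' @export
profile_summaries <- function(profiles) {
  if (inherits(profiles, "profile_set")) profiles <- profiles$profiles
  b <- ncol(profiles)
  centres <- (seq_len(b) - 0.5) / b * 1.2    # bin centres in units of radius
  central_bins <- which(centres < 0.4)
  ring_bins <- which(centres >= 0.6 & centres <= 1.0)
  data.frame(central = rowMeans(profiles[, central_bins, drop = FALSE]),
             ring = rowMeans(profiles[, ring_bins, drop = FALSE]))
}

# are the 99% confidence ellipses of two Gaussian clusters disjoint?
# boundary sampling + centre containment; q = chisq quantile, 2 df
.ellipses_disjoint <- function(mu1, S1, mu2, S2, level = 0.99, n_angle = 720L) {
  q <- stats::qchisq(level, df = 2)
  maha <- function(x, mu, S) {
    d <- x - mu
    as.numeric(d %*% solve(S, d))
  }
  if (maha(mu1, mu2, S2) <= q || maha(mu2, mu1, S1) <= q) return(FALSE)
  th <- seq(0, 2 * pi, length.out = n_angle + 1L)[-1]
  circ <- rbind(cos(th), sin(th)) * sqrt(q)
  b1 <- t(chol(S1)) %*% circ + mu1
  b2 <- t(chol(S2)) %*% circ + mu2
  inside <- function(pts, mu, S) {
    d <- sweep(pts, 1, mu)
    m <- colSums(d * solve(S, d))
    any(m <= q)
  }
  !(inside(b1, mu2, S2) || inside(b2, mu1, S1))
}

#' Cluster PC scores and label full/empty/uncertain
#'
#' Fits a two-component Gaussian mixture (full covariances) to the 2-D PCA
#' scores and anchors the labels physically: the cluster with the lower mean
#' central profile intensity — the darker centres — is "full", the other
#' "empty". Particles whose mixture posterior falls below
#' `posterior_threshold` are labelled "uncertain". A dataset-level
#' separation diagnostic reports whether the clusters' 99% confidence
#' ellipses (chi-square quantile, 2 df) are disjoint.
#'
#' When the mixture is degenerate — one component empty, the fit fails, or
#' the two components do not differ meaningfully in central intensity
#' (standardised difference below `degenerate_d`) — all particles are
#' assigned a single class chosen from the profile physics (mean central
#' darker than the inner-radius ring means full), the separation flag is
#' FALSE, and a warning is raised.
#'
#' @param scores n x 2 matrix of PC scores.
#' @param summaries data.frame from [profile_summaries()] (columns `central`,
#'   `ring`), one row per score row.
#' @param particle_id Optional ids (default 1..n).
#' @param posterior_threshold Uncertain cutoff in (0.5, 1); default 0.99.
#' @param degenerate_d Minimum standardised central-intensity difference
#'   between clusters for a genuine two-population split.
#' @return Object of class `classification_result`: `assignments` data.frame
#'   (`particle_id, pc1, pc2, posterior, label, manual`), `cluster_means`,
#'   `cluster_covs`, `cluster_labels`, `separated` (99% ellipses disjoint),
#'   `degenerate`, `posterior_threshold`.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_and_label <- function(scores, summaries, particle_id = NULL,
                              posterior_threshold = 0.99, degenerate_d = 2) {
  stopifnot(is.matrix(scores), ncol(scores) == 2,
            nrow(scores) == nrow(summaries),
            all(c("central", "ring") %in% names(summaries)),
            posterior_threshold > 0.5, posterior_threshold < 1)
  n <- nrow(scores)
  if (is.null(particle_id)) particle_id <- seq_len(n)

  single_class <- function(reason) {
    lab <- if (mean(summaries$central) < mean(summaries$ring)) "full" else "empty"
    warning("degenerate mixture (", reason, "): assigning all particles '",
            lab, "'")
    structure(list(
      assignments = data.frame(particle_id = particle_id,
                               pc1 = scores[, 1], pc2 = scores[, 2],
                               posterior = rep(1, n), label = lab,
                               manual = FALSE, stringsAsFactors = FALSE),
      cluster_means = NULL, cluster_covs = NULL, cluster_labels = lab,
      separated = FALSE, degenerate = TRUE,
      posterior_threshold = posterior_threshold),
      class = "classification_result")
  }
  fit <- tryCatch(
    Mclust(scores, G = 2, modelNames = "VVV", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters)) return(single_class("fit failed"))
  cls <- fit$classification
  if (length(unique(cls)) < 2 || min(table(cls)) < 2)
    return(single_class("one component empty"))

  m_central <- tapply(summaries$central, cls, mean)
  v_central <- tapply(summaries$central, cls, stats::var)
  d_sep <- abs(diff(m_central)) / sqrt(mean(v_central) + .Machine$double.eps)
  if (is.finite(d_sep) && d_sep < degenerate_d)
    return(single_class("clusters indistinct in central intensity"))

  full_k <- as.integer(names(which.min(m_central)))
  labels_by_k <- c("empty", "empty")
  labels_by_k[full_k] <- "full"

  post <- apply(fit$z, 1, max)
  label <- labels_by_k[cls]
  label[post < posterior_threshold] <- "uncertain"

  mu <- fit$parameters$mean                    # 2 x 2, cols = clusters
  sig <- fit$parameters$variance$sigma         # 2 x 2 x 2
  separated <- .ellipses_disjoint(mu[, 1], sig[, , 1], mu[, 2], sig[, , 2])

  structure(list(
    assignments = data.frame(particle_id = particle_id,
                             pc1 = scores[, 1], pc2 = scores[, 2],
                             posterior = post, label = label,
                             manual = FALSE, stringsAsFactors = FALSE),
    cluster_means = mu, cluster_covs = sig,
    cluster_labels = labels_by_k, separated = separated, degenerate = FALSE,
    posterior_threshold = posterior_threshold),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  tab <- table(factor(x$assignments$label,
                      levels = c("full", "empty", "uncertain")))
  cat("<classification_result>", nrow(x$assignments), "particles:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  99% confidence ellipses disjoint:", x$separated,
      if (x$degenerate) "(degenerate fit)" else "", "\n")
  invisible(x)
}

#' Manually assign a class to selected particles
#'
#' Mirrors the operator action of selecting cluster points on the scatter
#' plot and assigning them a class; overwritten labels are flagged as manual
#' in the provenance column.
#'
#' @param result A `classification_result`.
#' @param particle_id Ids to reassign (may be empty: no-op).
#' @param label One of full/empty/uncertain/excluded.
#' @return Updated `classification_result`.
#' @export
manual_assign <- function(result, particle_id, label) {
  stopifnot(inherits(result, "classification_result"))
  if (!label %in% c("full", "empty", "uncertain", "excluded"))
    stop("invalid label: ", label)
  if (!length(particle_id)) return(result)
  hit <- match(particle_id, result$assignments$particle_id)
  if (anyNA(hit))
    stop("unknown particle id(s): ",
         paste(particle_id[is.na(hit)], collapse = ", "))
  result$assignments$label[hit] <- label
  result$assignments$manual[hit] <- TRUE
  result
}

#' Scatter plot of PC scores coloured by class
#'
#' @param result A `classification_result`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the result.
#' @export
plot_scores <- function(result, ...) {
  stopifnot(inherits(result, "classification_result"))
  a <- result$assignments
  cols <- c(full = "#1b1b1b", empty = "#2166ac", uncertain = "#d95f02",
            excluded = "#999999")
  graphics::plot(a$pc1, a$pc2, col = cols[a$label], pch = 16, cex = 0.6,
                 xlab = "PC1", ylab = "PC2", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   bty = "n")
  invisible(result)
}
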