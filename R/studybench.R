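#' Spiking-series mixture design
#'
#' Describes a blend of a reference-full and a reference-empty AAV stock:
#' measured percent-full of each stock, capsid particle concentrations after
#' predilution, and the volume fraction of the full stock.
#'
#' @param F_f Measured %full of the reference-full stock (e.g. 79.32).
#' @param F_e Measured %full of the reference-empty stock (e.g. 1.17).
#' @param C_f,C_e Capsid particle concentrations (cp/mL) of the two stocks
#'   after predilution.
#' @param f Volume fraction of the full stock, in `[0, 1]`.
#' @return Object of class `mixture_design`.
#' @export
mixture_design <- function(F_f, F_e, C_f = 1, C_e = 1, f) {
  stopifnot(F_e >= 0, F_f <= 100, F_e <= F_f, C_f > 0, C_e > 0,
            f >= 0, f <= 1)
  structure(list(F_f = F_f, F_e = F_e, C_f = C_f, C_e = C_e, f = f),
            class = "mixture_design")
}

#' Theoretical percent-full of a mixture
#'
#' Particle-weighted blend of the two stocks' full fractions:
#' \deqn{\%F = 100 \frac{f C_f F_f/100 + (1-f) C_e F_e/100}
#'                     {f C_f + (1-f) C_e}}
#' which reduces to the linear blend `f * F_f + (1 - f) * F_e` at equal
#' concentrations (the predilution step's purpose). Monotone non-decreasing
#' in `f` and bounded by `[F_e, F_f]`.
#'
#' @param design A [mixture_design()].
#' @return Percent full of the mixture.
#' @examples
#' theoretical_percent_full(mixture_design(F_f = 79.32, F_e = 1.17, f = 1))
#' @export
theoretical_percent_full <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  with(design,
       100 * (f * C_f * F_f / 100 + (1 - f) * C_e * F_e / 100) /
         (f * C_f + (1 - f) * C_e))
}

#' Repeatability statistics over replicate measurements
#'
#' Sample mean, sd (n - 1 denominator) and relative standard deviation
#' `RSD = 100 * sd / mean` of replicate %full measurements, the ICH Q2(R1)
#' repeatability characteristic.
#'
#' @param values Numeric vector of replicate measurements (>= 2).
#' @return List `mean`, `sd`, `rsd` (percent).
#' @export
repeatability_rsd <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2, all(is.finite(values)))
  m <- mean(values)
  if (m == 0) stop("mean of replicates is zero; RSD undefined")
  s <- stats::sd(values)
  list(mean = m, sd = s, rsd = 100 * s / m)
}

#' Linearity of measured vs theoretical percent-full
#'
#' Ordinary least squares of the measured values on the theoretical mixture
#' values; a validated method returns slope near 1, intercept near 0 and
#' R-squared near 1 across the spiking series.
#'
#' @param theoretical,measured Paired %full values (>= 3 points).
#' @return List `slope`, `intercept`, `r_squared`, `fit` (the `lm`).
#' @export
linearity_fit <- function(theoretical, measured) {
  stopifnot(length(theoretical) == length(measured), length(theoretical) >= 3)
  if (stats::var(theoretical) <= 0)
    stop("theoretical values have zero variance; slope undefined")
  fit <- stats::lm(measured ~ theoretical)
  # summary.lm warns on exact lines ("essentially perfect fit"); an exact
  # line is a legitimate input here (oracle tests, noiseless recovery)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, fit = fit)
}

#' Percent-full equivalent from vg and cp titres
#'
#' The orthogonal wet-lab estimate: vector genomes (qPCR) per capsid
#' particle (ELISA), as a percentage. Values above 100 are allowed — the
#' ratio method can overcount genomes relative to capsids.
#'
#' @param vg Vector-genome titre(s), > 0 allowed 0.
#' @param cp Capsid-particle titre(s), > 0.
#' @param rounding `"integer"` (half-up, as printed in release tables) or
#'   `"raw"`.
#' @return Percent full equivalent, vectorised.
#' @examples
#' vg_cp_percent(1.79e14, 3.49e15)  # 5
#' @export
vg_cp_percent <- function(vg, cp, rounding = c("integer", "raw")) {
  rounding <- match.arg(rounding)
  stopifnot(length(vg) == length(cp), all(vg >= 0))
  if (any(cp <= 0)) stop("cp titre must be > 0")
  pct <- 100 * vg / cp
  if (rounding == "integer") round_half_up(pct) else pct
}

#' Regression of the vg/cp percent on the cryoTEM percent-full
#'
#' Orthogonal method comparison: OLS of the (unrounded) vg/cp percentage on
#' the cryoTEM %full across samples, flagging whether the slope exceeds 1 —
#' i.e. whether the titre-ratio method reads systematically higher than
#' direct imaging, increasingly so for fuller preparations.
#'
#' @param table data.frame with columns `cryotem_pct_full`,
#'   `vg_per_fraction`, `cp_per_fraction` (see [aav_table2()]).
#' @return List `slope`, `intercept`, `r_squared`, `slope_gt_1`, `fit`.
#' @export
orthogonal_regression_check <- function(table) {
  need <- c("cryotem_pct_full", "vg_per_fraction", "cp_per_fraction")
  stopifnot(all(need %in% names(table)))
  tab <- table[stats::complete.cases(table[, need]), ]
  if (nrow(tab) < 3) stop("need >= 3 samples with both cryoTEM and titres")
  pct <- vg_cp_percent(tab$vg_per_fraction, tab$cp_per_fraction, "raw")
  fit <- linearity_fit(tab$cryotem_pct_full, pct)
  fit$slope_gt_1 <- fit$slope > 1
  fit
}

#' Correlation between percent-full and biopotency
#'
#' Pearson correlation of a biopotency readout (in-vitro cell assay in
#' relative BPU, or in-vivo FIX activity in IU/mL) with the percent of full
#' particles.
#'
#' @param table data.frame with `theoretical_pct_full` and `invitro_bp` /
#'   `invivo_bp` columns (see [aav_table3()]).
#' @param which `"invitro"` or `"invivo"`.
#' @return Pearson correlation coefficient.
#' @export
potency_correlation <- function(table, which = c("invitro", "invivo")) {
  which <- match.arg(which)
  col <- if (which == "invitro") "invitro_bp" else "invivo_bp"
  stopifnot(all(c("theoretical_pct_full", col) %in% names(table)))
  ok <- stats::complete.cases(table[, c("theoretical_pct_full", col)])
  x <- table$theoretical_pct_full[ok]; y <- table[[col]][ok]
  if (length(x) < 3) stop("need >= 3 paired values")
  if (stats::var(x) <= 0 || stats::var(y) <= 0)
    stop("zero variance; correlation undefined")
  stats::cor(x, y)
}

#' Bundled assay tables
#'
#' Small CSV transcriptions of the published assay tables shipped with the
#' package: `aav_table2()` returns ultracentrifugation-fraction samples
#' S1.1--S1.10 with cryoTEM %full, qPCR vg titres, ELISA cp titres and the
#' printed vg/cp integer percentage; `aav_table3()` returns spiking-series
#' samples S2.1--S2.6 with theoretical %full and biopotency readouts.
#'
#' @return data.frame.
#' @export
aav_table2 <- function() {
  utils::read.csv(system.file("extdata", "sample_set1_table2.csv",
                              package = "capsidquant"),
                  stringsAsFactors = FALSE)
}

#' @rdname aav_table2
#' @export
aav_table3 <- function() {
  utils::read.csv(system.file("extdata", "sample_set2_table3.csv",
                              package = "capsidquant"),
                  stringsAsFactors = FALSE)
}
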