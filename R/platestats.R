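# Screening arithmetic and the polyclonal 96-well founder model.
#
# After electroporation the culture is distributed into a 96-well plate,
# so each well is seeded by a Poisson number of kanamycin-resistant
# founder bacteria (lambda = colonies/wells, typically ~1-4). Each founder
# independently carries the co-targeted loxP with probability f, so a well
# scores PCR-positive with probability 1 - exp(-lambda * f). Inverting
# this converts well counts back into per-colony co-targeting frequencies.

#' Colony-count frequency summary
#'
#' Exact fraction plus the two display conventions used in screening
#' tables: two significant figures and nearest whole percent.
#'
#' @param k Number of loxP-positive colonies (or wells).
#' @param n Total colonies (or wells) screened; must be positive.
#' @return List of class \code{freq_summary}: \code{k}, \code{n},
#'   \code{fraction}, \code{percent_2sf}, \code{percent_whole}.
#' @export
#' @examples
#' frequency_summary(23, 369)$percent_2sf  # 6.2
frequency_summary <- function(k, n) {
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  if (k < 0L || k > n) stop("k must lie in [0, n]", call. = FALSE)
  frac <- k / n
  structure(list(k = as.integer(k), n = as.integer(n), fraction = frac,
                 percent_2sf = signif(100 * frac, 2),
                 percent_whole = round(100 * frac)),
            class = "freq_summary")
}

#' @export
print.freq_summary <- function(x, ...) {
  cat(sprintf("<freq_summary> %d/%d = %s%% (%d%%)\n", x$k, x$n,
              format(x$percent_2sf), x$percent_whole))
  invisible(x)
}

#' Mean founders per well
#'
#' @param colonies Kanamycin-resistant CFU distributed across the plate.
#' @param wells Number of wells receiving culture.
#' @return The Poisson rate lambda = colonies / wells.
#' @export
#' @examples
#' founders_per_well(131, 96)  # ~1.36
founders_per_well <- function(colonies, wells) {
  if (wells <= 0L) stop("wells must be positive", call. = FALSE)
  colonies / wells
}

#' Predicted fraction of loxP-positive wells
#'
#' Founders per well are Poisson(lambda); each founder is independently
#' co-targeted with probability f; a well is positive when it received at
#' least one co-targeted founder. Hence P(positive) = 1 - exp(-lambda f).
#'
#' @param lambda Mean founders per well (>= 0).
#' @param f Per-colony co-targeting frequency in [0, 1].
#' @return Probability that a well scores positive.
#' @export
predict_positive_well_fraction <- function(lambda, f) {
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  1 - exp(-lambda * f)
}

#' Screen results container
#'
#' @param colonies Total kan-resistant CFU distributed.
#' @param wells Wells receiving culture (e.g. 95 when a plate carries
#'   control wells).
#' @param positives loxP-PCR-positive wells.
#' @param cotargeting_freq Optional known/true per-colony frequency.
#' @return List of class \code{plate_screen}.
#' @export
plate_screen <- function(colonies, wells, positives,
                         cotargeting_freq = NA_real_) {
  if (positives < 0L || positives > wells) {
    stop("positives must lie in [0, wells]", call. = FALSE)
  }
  if (!is.na(cotargeting_freq) &&
      (cotargeting_freq < 0 || cotargeting_freq > 1)) {
    stop("cotargeting_freq must lie in [0, 1]", call. = FALSE)
  }
  structure(list(colonies = as.integer(colonies), wells = as.integer(wells),
                 positives = as.integer(positives),
                 cotargeting_freq = cotargeting_freq),
            class = "plate_screen")
}

#' Estimate the per-colony co-targeting frequency from a plate screen
#'
#' Inverts the Poisson founder model: f_hat = -ln(1 - positives/wells) /
#' lambda, clamped to [0, 1], with a confidence interval obtained by
#' transforming an exact (Clopper-Pearson) binomial interval on
#' positives/wells.
#'
#' @param screen A \code{\link{plate_screen}}.
#' @param conf_level Confidence level for the interval.
#' @return List of class \code{freq_estimate}: \code{f_hat}, \code{ci}
#'   (length 2), \code{lambda}, \code{p_hat}.
#' @export
estimate_cotargeting_freq <- function(screen, conf_level = 0.95) {
  lambda <- founders_per_well(screen$colonies, screen$wells)
  if (lambda <= 0) stop("lambda must be positive to estimate f", call. = FALSE)
  if (screen$positives == screen$wells) {
    stop("all wells positive: the screen is saturated and f is ",
         "unidentifiable", call. = FALSE)
  }
  p_hat <- screen$positives / screen$wells
  to_f <- function(p) pmin(1, pmax(0, -log(1 - p) / lambda))
  ci_p <- stats::binom.test(screen$positives, screen$wells,
                            conf.level = conf_level)$conf.int
  structure(list(f_hat = to_f(p_hat),
                 ci = to_f(pmin(ci_p, 1 - 1e-12)),
                 lambda = lambda, p_hat = p_hat),
            class = "freq_estimate")
}

#' @export
print.freq_estimate <- function(x, ...) {
  cat(sprintf("<freq_estimate> f = %.4f (CI %.4f-%.4f), lambda = %.2f\n",
              x$f_hat, x$ci[1], x$ci[2], x$lambda))
  invisible(x)
}

#' Risk that every pooled BAC clone is incorrect
#'
#' Pooling n independent clones for one project fails only when all n are
#' incorrect: risk = per_clone_bad ^ n.
#'
#' @param per_clone_bad Probability a single library clone is incorrect
#'   (misannotated or rearranged).
#' @param n_clones Number of independent clones pooled (>= 1).
#' @return Failure probability.
#' @export
#' @examples
#' pooled_bac_failure_risk(0.10, 2)  # 0.01
pooled_bac_failure_risk <- function(per_clone_bad, n_clones) {
  if (per_clone_bad < 0 || per_clone_bad > 1) {
    stop("per_clone_bad must lie in [0, 1]", call. = FALSE)
  }
  if (n_clones < 1L) stop("n_clones must be at least 1", call. = FALSE)
  per_clone_bad^n_clones
}

#' Simulate one polyclonal plate screen
#'
#' Draws Poisson founders per well and binomial co-targeting per founder;
#' a well is positive when at least one founder is co-targeted. Uses the
#' current RNG state (set a seed for reproducibility).
#'
#' @param lambda Mean founders per well.
#' @param f True per-colony co-targeting frequency.
#' @param wells Number of wells.
#' @return A \code{\link{plate_screen}} with \code{cotargeting_freq = f}.
#' @export
simulate_plate <- function(lambda, f, wells = 96L) {
  founders <- stats::rpois(wells, lambda)
  hits <- stats::rbinom(wells, founders, f)
  plate_screen(colonies = sum(founders), wells = wells,
               positives = sum(hits > 0L), cotargeting_freq = f)
}
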