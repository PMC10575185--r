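#' Calibrant masses of the instrument response study
#'
#' The 14 synthetic peptide and protein calibrants (Da) used to quantify how
#' MALDI-TOF signal falls with molecular weight, spanning angiotensin II
#' (1046.2 Da) to bovine serum albumin (66,429.9 Da).
#'
#' @format Numeric vector of 14 masses in Da.
#' @export
calibrant_masses <- c(
  1046.2, 1296.5, 1672.9, 2093.5, 2465.7,          # peptide mix 1
  3495.9, 5733.6, 6511.5, 8564.8,                  # peptide mix 3
  12360.1, 16951.5, 23980.9, 46670.9, 66429.9      # protein standards
)

#' Fit the mass-dependent signal-attenuation line
#'
#' Ordinary least squares of `log10(peak_height / spotted_amount)` on
#' `log10(mass)`: the empirical contract is a power law
#' `height/amount ~ mass^slope` with slope expected near -2 (about two log
#' units of signal lost per decade of molecular weight). Amount units cancel
#' in the slope, so any consistent unit is accepted.
#'
#' @param obs data.frame with columns `mass` (Da), `amount` (spotted amount,
#'   arbitrary consistent units) and `height` (peak height, signal units);
#'   all positive. At least 3 observations spanning at least one decade of
#'   mass.
#' @return A list of class `attenuation_fit` with `slope`, `intercept`,
#'   `r_squared` and the underlying [stats::lm] fit.
#' @examples
#' obs <- data.frame(mass = c(1e3, 1e4, 1e5), amount = 1,
#'                   height = c(1, 1e-2, 1e-4))
#' fit_attenuation(obs)$slope   # exactly -2
#' @export
fit_attenuation <- function(obs) {
  required <- c("mass", "amount", "height")
  if (!all(required %in% names(obs))) {
    stop("'obs' needs columns mass, amount, height")
  }
  if (any(obs$mass <= 0) || any(obs$amount <= 0) || any(obs$height <= 0)) {
    stop("mass, amount and height must all be > 0")
  }
  if (nrow(obs) < 3) stop("need at least 3 calibrant observations")
  lx <- log10(obs$mass)
  if (diff(range(lx)) < 1) {
    stop("calibrant masses must span at least one decade")
  }
  ly <- log10(obs$height / obs$amount)
  fit <- stats::lm(ly ~ lx)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 lm = fit),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf(
    "<attenuation_fit> slope %.4f log10-signal per log10-Da (r^2 %.4f)\n",
    x$slope, x$r_squared))
  invisible(x)
}

#' Predicted signal enhancement from digesting a parent protein
#'
#' Under a power-law attenuation of magnitude `s`, detecting a peptide
#' fragment of mass `m` in place of its parent protein of mass `M` gains a
#' factor `(M / m)^s` in signal. With the default slope magnitude of 2 and a
#' prototypical 1 kDa tryptic fragment, a 10 kDa parent gains 100-fold and a
#' 100 kDa parent 10,000-fold.
#'
#' @param parent_mass parent protein mass in Da (> 0); vectorized.
#' @param fragment_mass fragment mass in Da (> 0), default 1000.
#' @param slope_magnitude attenuation slope magnitude (>= 0), default 2.
#' @return Fold enhancement (dimensionless).
#' @examples
#' enhancement_factor(10^3.5)   # approx. 10
#' enhancement_factor(c(1e4, 1e5))
#' @export
enhancement_factor <- function(parent_mass, fragment_mass = 1000,
                               slope_magnitude = 2) {
  if (any(parent_mass <= 0) || any(fragment_mass <= 0)) {
    stop("masses must be > 0")
  }
  if (any(slope_magnitude < 0)) stop("slope_magnitude must be >= 0")
  (parent_mass / fragment_mass)^slope_magnitude
}

#' Summarize a proteome's mass distribution
#'
#' Reports the fraction of protein masses above a threshold (default
#' 10 kDa, where MALDI-TOF detection of intact proteins becomes rare) and a
#' histogram over decade-spaced (log10) mass bins.
#'
#' @param masses numeric vector of protein masses in Da (non-empty, > 0).
#' @param threshold mass threshold in Da.
#' @param bins_per_decade histogram resolution; default 4.
#' @return List with `fraction_above`, `threshold`, `n`, and `histogram`
#'   (data.frame of log10-spaced bin edges and counts summing to `n`).
#' @export
proteome_mass_summary <- function(masses, threshold = 10000,
                                  bins_per_decade = 4) {
  if (!length(masses)) stop("empty mass list")
  if (any(masses <= 0)) stop("masses must be > 0")
  lm <- log10(masses)
  lo <- floor(min(lm) * bins_per_decade) / bins_per_decade
  hi <- ceiling(max(lm) * bins_per_decade) / bins_per_decade
  if (hi <= lo) hi <- lo + 1 / bins_per_decade
  breaks <- seq(lo, hi, by = 1 / bins_per_decade)
  counts <- table(cut(lm, breaks, include.lowest = TRUE))
  list(fraction_above = mean(masses > threshold),
       threshold = threshold,
       n = length(masses),
       histogram = data.frame(log10_lower = breaks[-length(breaks)],
                              log10_upper = breaks[-1],
                              count = as.integer(counts)))
}

#' Generate a synthetic calibrant response table
#'
#' The raw calibrant intensities behind the attenuation fit are not
#' distributed with the instrument study, so the package ships this seeded
#' synthetic generator instead: heights follow the power law
#' `height = amount * 10^intercept * mass^slope` with multiplicative
#' log10-normal scatter.
#'
#' @param masses calibrant masses in Da; default [calibrant_masses].
#' @param slope power-law slope (default -2).
#' @param intercept log10 height/amount at 1 Da (default 6, an arbitrary
#'   instrument gain).
#' @param sigma_log10 standard deviation of log10 scatter (default 0.1).
#' @param amount spotted amount(s), recycled (default 1).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return data.frame with columns `mass`, `amount`, `height` suitable for
#'   [fit_attenuation()].
#' @export
simulate_calibrants <- function(masses = calibrant_masses, slope = -2,
                                intercept = 6, sigma_log10 = 0.1,
                                amount = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  amount <- rep_len(amount, length(masses))
  ly <- intercept + slope * log10(masses) +
    stats::rnorm(length(masses), 0, sigma_log10)
  data.frame(mass = masses, amount = amount, height = amount * 10^ly)
}

#' Read a calibrant CSV (columns mass, amount, height)
#' @param path CSV path.
#' @return data.frame for [fit_attenuation()].
#' @export
read_calibrants <- function(path) {
  df <- utils::read.csv(path)
  required <- c("mass", "amount", "height")
  if (!all(required %in% names(df))) {
    stop("calibrant file needs columns mass, amount, height")
  }
  df[required]
}
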