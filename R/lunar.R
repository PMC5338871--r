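# Lunar-phase covariate: signed lunar luminosity, waxing positive and waning
# negative, derived from the elapsed fraction of the synodic month.

LUNAR_SYNODIC <- 29.53059  # mean synodic month, days

LUNAR_PHASES <- c("new", "waxing crescent", "waxing half", "waxing gibbous",
                  "full", "waning gibbous", "waning half", "waning crescent")

#' New-moon reference times from the mean lunation
#'
#' Computes new-moon epochs by extrapolating the mean synodic month from the
#' 2000-01-06 18:14 UT new moon. This is a synthetic ephemeris: true new
#' moons deviate from the mean lunation by up to ~0.6 days, which shifts the
#' phase angle by at most ~7 degrees; adequate for a luminosity covariate.
#'
#' @param from,to Date range to cover.
#' @return data.frame with columns `datetime` (ISO string, UT) and `days`
#'   (fractional days since 1970-01-01).
#' @export
mean_lunation_new_moons <- function(from = as.Date("1985-01-01"),
                                    to = as.Date("2040-12-31")) {
  t0 <- as.numeric(as.Date("2000-01-06")) + 18.24 / 24
  k <- seq(floor((as.numeric(from) - t0) / LUNAR_SYNODIC) - 1,
           ceiling((as.numeric(to) - t0) / LUNAR_SYNODIC) + 1)
  days <- t0 + k * LUNAR_SYNODIC
  data.frame(
    datetime = format(as.POSIXct(days * 86400, origin = "1970-01-01", tz = "UTC"),
                      "%Y-%m-%dT%H:%M:%SZ"),
    days = days
  )
}

.lunar_env <- new.env(parent = emptyenv())

#' Packaged new-moon reference table
#'
#' Reads (and caches) the new-moon ephemeris CSV shipped with the package,
#' which was generated by [mean_lunation_new_moons()].
#' @return data.frame with columns `datetime` and `days`.
#' @export
reef_new_moons <- function() {
  if (is.null(.lunar_env$new_moons)) {
    path <- system.file("extdata", "new_moons_mean_lunation_synthetic.csv",
                        package = "reefspawn")
    .lunar_env$new_moons <- if (nzchar(path)) {
      utils::read.csv(path, stringsAsFactors = FALSE)
    } else {
      mean_lunation_new_moons()
    }
  }
  .lunar_env$new_moons
}

#' Signed lunar luminosity (Lunar3) for calendar dates
#'
#' Phase angle `theta = 2*pi*(days since previous new moon)/29.53059`;
#' illuminated fraction `f = (1 - cos(theta))/2`. The covariate is `+f` for
#' waxing moons (`theta` in `[0, pi]`) and `-f` for waning moons, so it runs
#' from 0 at new moon through +1 approaching full, switching to -1 just past
#' full, and back to 0. With `quarter_round = TRUE` the value is snapped to
#' the nearest multiple of 0.25. The phase category comes from the eight
#' octants of `theta`. Dates are evaluated at local noon.
#'
#' @param dates a `Date` vector (or coercible).
#' @param quarter_round snap the value to the nearest quarter (default `FALSE`).
#' @param new_moons reference table from [reef_new_moons()].
#' @return data.frame with columns `value` (in `[-1, 1]`), `phase` (factor
#'   with the eight phase categories) and `theta` (radians in `[0, 2*pi)`).
#' @export
lunar3 <- function(dates, quarter_round = FALSE, new_moons = reef_new_moons()) {
  t <- as.numeric(as.Date(dates)) + 0.5
  nm <- new_moons$days
  idx <- findInterval(t, nm)
  if (any(idx < 1)) stopf("date(s) before the first reference new moon")
  theta <- 2 * pi * (t - nm[idx]) / LUNAR_SYNODIC
  theta <- theta %% (2 * pi)
  f <- (1 - cos(theta)) / 2
  value <- ifelse(theta <= pi, f, -f)
  if (quarter_round) value <- round(value * 4) / 4
  octant <- floor(((theta + pi / 8) %% (2 * pi)) / (pi / 4)) + 1
  data.frame(
    value = value,
    phase = factor(LUNAR_PHASES[octant], levels = LUNAR_PHASES),
    theta = theta
  )
}
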