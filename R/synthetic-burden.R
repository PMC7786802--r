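# Stage seeds are derived from the master seed so that each generator stage
# is reproducible in isolation; kept well below 2^31.
seed_for <- function(seed, stage) {
  offset <- c(burden = 101L, articles = 211L, validation = 307L,
              mapping = 401L, countries = 503L, counts = 601L,
              adjust = 701L, sizes = 809L, regress = 907L)[[stage]]
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

check_years <- function(years) {
  years <- sort(unique(as.integer(years)))
  if (length(years) == 0) stop("year range is empty")
  years
}

#' Generate a synthetic disease-burden panel
#'
#' Emulates an annual Global Burden of Disease panel: per-condition DALYs in
#' thousands following a lognormal level law with a smooth linear trend and a
#' mild random-walk wiggle, split into high-SDI and low/middle-SDI parts, with
#' deaths, YLD and YLL as consistent components (YLD + YLL = DALYs exactly).
#'
#' When `truth$noise_sd == 0` and the contemporaneous elasticity is non-zero,
#' the DALY series is additionally "snapped" so that the implied expected
#' article count \eqn{\exp(\alpha_t + \beta \log D_{it} + \ldots)} is an exact
#' positive integer for every condition-year: the publication law then holds
#' exactly on discrete article counts, which is what makes noise-free
#' parameter recovery exact to numerical precision.
#'
#' @param n_conditions Number of conditions (>= 2); the first
#'   `n_conditions` GBD category names are used as labels.
#' @param years Integer vector of years (inclusive range), e.g. `1990:2017`.
#' @param truth A [ground_truth()] object.
#' @return A data.frame with columns `condition`, `year`, `dalys`,
#'   `dalys_high_sdi`, `dalys_lowmid_sdi`, `deaths`, `yld`, `yll`
#'   (all burdens in thousands).
#' @export
#' @examples
#' b <- generate_burden(4, 2000:2005, ground_truth(seed = 1))
#' head(b)
generate_burden <- function(n_conditions, years, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_conditions < 2) stop("n_conditions must be >= 2")
  years <- check_years(years)
  ny <- length(years)
  set.seed(seed_for(truth$seed, "burden"))

  conds <- condition_names(n_conditions)
  base <- rnorm(n_conditions, truth$daly_meanlog, truth$daly_sdlog)
  trend <- rnorm(n_conditions, 0.005, truth$daly_trend_sd)

  share0 <- truth$sdi_share
  if (is.null(share0)) {
    share0 <- rbeta(n_conditions, 2, 4)
  } else {
    share0 <- rep_len(share0, n_conditions)
  }
  death_frac <- runif(n_conditions, 0.005, 0.12)
  yld_frac <- rbeta(n_conditions, 2, 2)

  rows <- vector("list", n_conditions)
  for (i in seq_len(n_conditions)) {
    walk <- cumsum(rnorm(ny, 0, truth$daly_jitter))
    logD <- base[i] + trend[i] * (seq_len(ny) - 1) + walk
    s <- share0[i]
    if (s > 0 && s < 1) {
      # slow drift in the SDI split so the location ratio varies within panel
      s <- stats::plogis(stats::qlogis(s) + cumsum(rnorm(ny, 0, 0.08)))
    } else {
      s <- rep(s, ny)
    }
    rows[[i]] <- data.frame(
      condition = conds[i], year = years,
      log_dalys = logD, sdi_share = s,
      death_frac = death_frac[i], yld_frac = yld_frac[i],
      stringsAsFactors = FALSE
    )
  }
  b <- do.call(rbind, rows)

  if (truth$noise_sd == 0) {
    b$log_dalys <- snap_log_dalys(b, truth, years)
  }

  b$dalys <- exp(b$log_dalys)
  b$dalys_high_sdi <- b$dalys * b$sdi_share
  b$dalys_lowmid_sdi <- b$dalys - b$dalys_high_sdi
  b$deaths <- b$dalys * b$death_frac
  b$yld <- b$dalys * b$yld_frac
  b$yll <- b$dalys - b$yld
  b[c("condition", "year", "dalys", "dalys_high_sdi", "dalys_lowmid_sdi",
      "deaths", "yld", "yll")]
}

# Deterministic-mode adjustment: solve log D_t so that the expected count is
# an exact positive integer, sequentially within each condition (earlier
# snapped values feed later lags).  Divisor is the contemporaneous lag-0
# coefficient except in year 1, where clamped lags fold onto the same value.
snap_log_dalys <- function(b, truth, years) {
  w <- if (is.null(truth$lag_weights)) truth$true_elasticity else truth$lag_weights
  if (w[1] == 0) return(b$log_dalys)
  ye <- resolve_year_effects(truth, years)
  bloc <- truth$location_effect
  out <- b$log_dalys
  for (cond in unique(b$condition)) {
    idx <- which(b$condition == cond)
    idx <- idx[order(b$year[idx])]
    logD <- out[idx]
    s <- b$sdi_share[idx]
    logratio <- ifelse(s > 0 & s < 1, log(s / (1 - s)), 0)
    L <- length(w) - 1
    for (t in seq_along(idx)) {
      lag_idx <- pmax(1L, t - seq_len(max(L, 0)))
      divisor <- w[1] + if (L > 0) sum(w[-1][lag_idx == t]) else 0
      if (divisor == 0) next
      lag_part <- if (L > 0) sum(w[-1][lag_idx != t] * logD[lag_idx[lag_idx != t]]) else 0
      eta <- ye[[t]] + divisor * logD[t] + lag_part + bloc * logratio[t]
      n <- max(1, round(exp(eta)))
      logD[t] <- (log(n) - ye[[t]] - lag_part - bloc * logratio[t]) / divisor
    }
    out[idx] <- logD
  }
  out
}

# Linear predictor of log expected article count for each burden row.
# Lags clamp at the series start (documented convention; fits on a common
# sample never touch the clamped rows).
linear_predictor <- function(burden, truth) {
  w <- if (is.null(truth$lag_weights)) truth$true_elasticity else truth$lag_weights
  years <- sort(unique(burden$year))
  ye <- resolve_year_effects(truth, years)
  eta <- numeric(nrow(burden))
  for (cond in unique(burden$condition)) {
    idx <- which(burden$condition == cond)
    idx <- idx[order(burden$year[idx])]
    logD <- log(burden$dalys[idx])
    e <- ye[match(burden$year[idx], years)] + w[1] * logD
    L <- length(w) - 1
    if (L > 0) {
      for (j in seq_len(L)) {
        lagD <- logD[pmax(1L, seq_along(logD) - j)]
        e <- e + w[j + 1] * lagD
      }
    }
    if (truth$location_effect != 0) {
      hi <- burden$dalys_high_sdi[idx]
      lo <- burden$dalys_lowmid_sdi[idx]
      ratio <- ifelse(lo > 0, hi / lo, NA_real_)
      if (any(!is.finite(ratio) | ratio <= 0))
        stop("location_effect requires a positive, finite DALY location ratio")
      e <- e + truth$location_effect * log(ratio)
    }
    eta[idx] <- e
  }
  eta
}

# Draw article counts for every burden row.  Caller controls the RNG state.
draw_counts <- function(burden, truth) {
  eta <- linear_predictor(burden, truth)
  if (truth$noise_sd == 0) {
    n <- as.integer(round(exp(eta)))
  } else {
    lambda <- exp(eta + rnorm(length(eta), 0, truth$noise_sd))
    n <- rpois(length(eta), lambda)
  }
  data.frame(condition = burden$condition, year = burden$year,
             eta = eta, count = n, stringsAsFactors = FALSE)
}

#' Simulate a condition-year regression panel directly
#'
#' Fast path for simulation studies: generates a burden panel and draws
#' article counts from the publication law without materialising individual
#' article records.  The result is directly consumable by [burden_fit()].
#'
#' @inheritParams generate_burden
#' @return A data.frame with columns `category`, `year`, `rct_count`,
#'   `dalys`, `dalys_high_sdi`, `dalys_lowmid_sdi`, `daly_ratio`.
#' @export
#' @examples
#' p <- simulate_panel(22, 1990:2017, ground_truth(noise_sd = 0, seed = 3))
#' fit <- burden_fit(p)
#' coef(fit)[["log_dalys"]]
simulate_panel <- function(n_conditions = 22, years = 1990:2017,
                           truth = ground_truth()) {
  burden <- generate_burden(n_conditions, years, truth)
  set.seed(seed_for(truth$seed, "counts"))
  cnt <- draw_counts(burden, truth)
  data.frame(
    category = burden$condition, year = burden$year,
    rct_count = cnt$count,
    dalys = burden$dalys,
    dalys_high_sdi = burden$dalys_high_sdi,
    dalys_lowmid_sdi = burden$dalys_lowmid_sdi,
    daly_ratio = ifelse(burden$dalys_lowmid_sdi > 0,
                        burden$dalys_high_sdi / burden$dalys_lowmid_sdi,
                        NA_real_),
    stringsAsFactors = FALSE
  )
}
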