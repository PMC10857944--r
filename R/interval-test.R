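#' Diel activity pattern of a species
#'
#' The multiset of time-of-day values (seconds after midnight) of a species'
#' contacts, pooled across stations. Used by the randomization null of the
#' time-interval test: follower contacts are re-timestamped with times drawn
#' from this pattern. Two samplers are available: assumption-free empirical
#' resampling with replacement (default), or a circular kernel-density
#' estimate that jitters each resampled time with von Mises noise of
#' concentration `kappa`, wrapping correctly at midnight.
#'
#' @param contacts a `contact_table`.
#' @param species canonical species label.
#' @param method `"empirical"` or `"vonmises"`.
#' @param kappa von Mises concentration of the KDE kernel (larger is
#'   narrower; default 50, roughly a 20-minute kernel SD).
#' @return An `activity_pattern` object with the clock times in seconds.
#' @export
activity_pattern <- function(contacts, species,
                             method = c("empirical", "vonmises"), kappa = 50) {
  stopifnot(inherits(contacts, "contact_table"))
  method <- match.arg(method)
  species <- canonical_label(species)
  t <- contacts$timestamp[contacts$species == species]
  structure(list(species = species,
                 clock_times = as.numeric(t) %% 86400,
                 method = method, kappa = kappa),
            class = "activity_pattern")
}

# draw n clock times (seconds in [0, 86400)) from an activity pattern
sample_activity <- function(activity, n) {
  pool <- activity$clock_times
  if (!length(pool)) stop_ctti("activity pattern is empty")
  base <- pool[sample.int(length(pool), n, replace = TRUE)]
  if (activity$method == "vonmises" && n > 0) {
    noise <- rvonmises(n, 0, activity$kappa) * 86400 / (2 * pi)
    base <- (base + noise) %% 86400
  }
  base
}

# vectorized Best-Fisher von Mises sampler, angles in (-pi, pi] around mu
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(((stats::runif(n, -pi, pi) + mu + pi) %% (2 * pi)) - pi)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    u1 <- stats::runif(m); z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(stats::runif(sum(keep)) - 0.5) * acos(f[keep])
    out <- c(out, theta)
  }
  ((out[seq_len(n)] + mu + pi) %% (2 * pi)) - pi
}

# --- shared fast machinery -------------------------------------------------
# station-indexed context so the per-replicate work of the null loop is a
# handful of vectorized operations
BIG_KEY <- 1e9  # > any within-survey relative time in seconds

build_interval_ctx <- function(contacts, leader, follower, dataset,
                               pairing_mode = "most_recent") {
  dep <- dataset$deployments
  st_levels <- dep$station_id
  base <- min(as.numeric(dep$start))

  lsub <- contacts[contacts$species == leader, , drop = FALSE]
  fsub <- contacts[contacts$species == follower, , drop = FALSE]

  lst <- match(lsub$station_id, st_levels)
  lsec <- as.numeric(lsub$timestamp) - base
  o <- order(lst * BIG_KEY + lsec)
  lst <- lst[o]; lsec <- lsec[o]

  list(
    pairing_mode = pairing_mode,
    st_levels = st_levels,
    base = base,
    start_sec = as.numeric(dep$start) - base,
    end_sec = as.numeric(dep$end) - base,
    # midnight of each station's first active calendar date, and the number
    # of active dates (any date whose day intersects [start, end))
    date0_sec = floor(as.numeric(dep$start) / 86400) * 86400 - base,
    lkey = lst * BIG_KEY + lsec,
    lst = lst, lsec = lsec,
    fst = match(fsub$station_id, st_levels),
    fsec = as.numeric(fsub$timestamp) - base
  )
}

# number of active calendar dates per station, derived from ctx
ctx_n_dates <- function(ctx) {
  first_mid <- ctx$date0_sec
  # last instant is end - epsilon; its date index:
  last_mid <- floor((ctx$end_sec - 1e-6 + ctx$base) / 86400) * 86400 - ctx$base
  pmax(1L, as.integer(round((last_mid - first_mid) / 86400)) + 1L)
}

# intervals (hours) from follower events (st, sec) to most recent preceding
# leader event at the same station; optionally first-follower-per-leader only
compute_intervals <- function(st, sec, ctx) {
  if (!length(sec) || !length(ctx$lsec)) return(numeric(0))
  key <- st * BIG_KEY + sec
  idx <- findInterval(key, ctx$lkey)
  ok <- idx > 0L
  ok[ok] <- ctx$lst[idx[ok]] == st[ok]
  if (ctx$pairing_mode == "first_after_leader") {
    ord <- order(key)
    ok_ord <- ok[ord]
    first <- !duplicated(idx[ord]) & ok_ord
    keep <- logical(length(key)); keep[ord] <- first
    ok <- keep
  }
  (sec[ok] - ctx$lsec[idx[ok]]) / 3600
}

# one null draw of follower event times; returns seconds on the ctx scale
draw_null_follower <- function(ctx, activity, max_tries = 1000) {
  st <- ctx$fst
  n <- length(st)
  n_dates <- ctx_n_dates(ctx)
  t <- numeric(n)
  todo <- seq_len(n)
  tries <- 0
  while (length(todo)) {
    d <- floor(stats::runif(length(todo)) * n_dates[st[todo]])
    tod <- sample_activity(activity, length(todo))
    t[todo] <- ctx$date0_sec[st[todo]] + d * 86400 + tod
    bad <- t[todo] < ctx$start_sec[st[todo]] | t[todo] >= ctx$end_sec[st[todo]]
    todo <- todo[bad]
    tries <- tries + 1
    if (tries > max_tries)
      stop_ctti("could not place a null follower event inside the deployment window")
  }
  t
}

# ---------------------------------------------------------------------------

#' Leader-to-follower time intervals at shared stations
#'
#' For a directed species pair, merges both species' contacts per station in
#' time order and emits, for every follower contact preceded by at least one
#' leader contact at that station, the time since the most recent preceding
#' leader contact. Intervals are pooled across stations; follower contacts
#' with no preceding leader at their station contribute nothing. With
#' `pairing_mode = "first_after_leader"` only the first follower contact
#' after each leader contact contributes.
#'
#' @param contacts a `contact_table`.
#' @param leader,follower canonical species labels (distinct).
#' @param dataset the source [survey_dataset()].
#' @param pairing_mode `"most_recent"` (default) or `"first_after_leader"`.
#' @param max_lag_hours optional upper bound; intervals longer than this are
#'   dropped (default `Inf`, no cap).
#' @return Numeric vector of intervals in hours.
#' @export
leader_follower_intervals <- function(contacts, leader, follower, dataset,
                                      pairing_mode = c("most_recent",
                                                       "first_after_leader"),
                                      max_lag_hours = Inf) {
  pairing_mode <- match.arg(pairing_mode)
  leader <- canonical_label(leader); follower <- canonical_label(follower)
  if (leader == follower) stop_ctti("leader and follower must differ")
  ctx <- build_interval_ctx(contacts, leader, follower, dataset, pairing_mode)
  iv <- compute_intervals(ctx$fst, ctx$fsec, ctx)
  iv[iv <= max_lag_hours]
}

#' Re-timestamp follower contacts under the null of no association
#'
#' Produces one null replicate of the contact table: every contact of the
#' follower species keeps its station but receives a new timestamp composed
#' of a date drawn uniformly from that station's active calendar dates and a
#' time of day drawn from the follower's diel activity pattern (a draw
#' falling outside the deployment window is redrawn). All other species'
#' contacts are untouched and per-station follower counts are conserved, so
#' the null breaks only the temporal linkage between the pair.
#'
#' @param contacts a `contact_table`.
#' @param follower canonical species label.
#' @param activity an [activity_pattern()] for the follower.
#' @param dataset the source [survey_dataset()].
#' @param seed optional integer seed for reproducibility.
#' @return A `contact_table` of the same dimensions and ordering class.
#' @export
randomize_follower <- function(contacts, follower, activity, dataset,
                               seed = NULL) {
  stopifnot(inherits(contacts, "contact_table"))
  follower <- canonical_label(follower)
  if (!length(activity$clock_times) &&
      any(contacts$species == follower))
    stop_ctti("activity pattern is empty")
  if (!is.null(seed)) set.seed(seed)
  ctx <- build_interval_ctx(contacts, leader = "\r", follower = follower,
                            dataset)
  out <- contacts
  is_f <- contacts$species == follower
  if (any(is_f)) {
    sec <- draw_null_follower(ctx, activity)
    out$timestamp[is_f] <- as.POSIXct(sec + ctx$base, tz = "UTC",
                                      origin = "1970-01-01")
  }
  out
}

#' Null distribution of the median leader-to-follower interval
#'
#' Repeatedly re-timestamps the follower's contacts with [randomize_follower()]'s
#' mechanism, recomputes the pooled leader-to-follower intervals and takes
#' their median, building the distribution of medians expected when the
#' leader does not influence the follower. Replicates in which no interval
#' can be formed are recorded as invalid and excluded.
#'
#' @inheritParams leader_follower_intervals
#' @param reps number of null replicates (default 1000).
#' @param seed master seed; each replicate uses a deterministically derived
#'   substream so results do not depend on execution order.
#' @param activity_method,kappa passed to [activity_pattern()].
#' @return List with `null_medians` (valid replicates only),
#'   `n_invalid_replicates` and `unreliable` (TRUE when more than 20% of
#'   replicates were invalid).
#' @export
null_distribution <- function(contacts, leader, follower, dataset,
                              reps = 1000, seed = 1,
                              pairing_mode = c("most_recent",
                                               "first_after_leader"),
                              max_lag_hours = Inf,
                              activity_method = c("empirical", "vonmises"),
                              kappa = 50) {
  pairing_mode <- match.arg(pairing_mode)
  activity_method <- match.arg(activity_method)
  leader <- canonical_label(leader); follower <- canonical_label(follower)
  activity <- activity_pattern(contacts, follower, activity_method, kappa)
  ctx <- build_interval_ctx(contacts, leader, follower, dataset, pairing_mode)
  stream <- label_stream(leader, follower)

  meds <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, stream, r))
    sec <- draw_null_follower(ctx, activity)
    iv <- compute_intervals(ctx$fst, sec, ctx)
    iv <- iv[iv <= max_lag_hours]
    if (length(iv)) meds[r] <- stats::median(iv)
  }
  n_invalid <- sum(is.na(meds))
  list(null_medians = meds[!is.na(meds)],
       n_invalid_replicates = n_invalid,
       unreliable = n_invalid > 0.2 * reps)
}

# deterministic RNG stream id from a directed pair's labels
label_stream <- function(leader, follower) {
  s <- utf8ToInt(paste0(leader, ">", follower))
  as.integer(sum(s * (seq_along(s) %% 97 + 1)) %% 1000003L)
}

#' Two-sided randomization p-value from a null exceedance proportion
#'
#' Given `Q`, the proportion of null medians greater than the observed
#' median, the two-sided p-value of the time-interval test is
#' `p = min(Q, 1 - Q) * 2`, capped at 1.
#'
#' @param Q proportion in `[0, 1]`.
#' @return The two-sided p-value.
#' @export
interval_p_value <- function(Q) {
  stopifnot(is.numeric(Q), all(Q >= 0 & Q <= 1))
  pmin(1, 2 * pmin(Q, 1 - Q))
}

#' Spatiotemporal time-interval test for one directed species pair
#'
#' Tests whether the arrival of a leading species at a camera station
#' shortens (attraction) or lengthens (avoidance) the time until a follower
#' species is detected there. The observed statistic is the median of the
#' pooled leader-to-follower intervals; the null distribution is built by
#' re-timestamping follower contacts with random deployment dates and diel
#' activity-pattern times ([null_distribution()]). With `Q` the proportion
#' of null medians greater than the observed median (ties count one half),
#' the two-sided p-value is `min(Q, 1 - Q) * 2`. A positive percent
#' difference, `100 * (median(null) - observed) / median(null)`, means the
#' observed median is shorter than expected — the attraction direction.
#'
#' @inheritParams null_distribution
#' @return An `interval_test` object with fields `leader`, `follower`,
#'   `observed_median_hours`, `null_medians`, `Q`, `p_two_sided`,
#'   `pct_difference`, `band_95` (2.5th and 97.5th null percentiles),
#'   `n_intervals_observed`, `n_invalid_replicates`, `unreliable`,
#'   `testable`, and the settings used. `p_two_sided` of exactly 0 is
#'   printed as `< 1/reps`. Supports `print` and `plot`.
#' @export
interval_test <- function(contacts, leader, follower, dataset,
                          reps = 1000, seed = 1,
                          pairing_mode = c("most_recent", "first_after_leader"),
                          max_lag_hours = Inf,
                          activity_method = c("empirical", "vonmises"),
                          kappa = 50) {
  pairing_mode <- match.arg(pairing_mode)
  activity_method <- match.arg(activity_method)
  leader <- canonical_label(leader); follower <- canonical_label(follower)

  obs <- leader_follower_intervals(contacts, leader, follower, dataset,
                                   pairing_mode, max_lag_hours)
  res <- structure(list(
    leader = leader, follower = follower,
    observed_median_hours = NA_real_, null_medians = numeric(0),
    Q = NA_real_, p_two_sided = NA_real_, pct_difference = NA_real_,
    band_95 = c(NA_real_, NA_real_),
    n_intervals_observed = length(obs),
    n_invalid_replicates = NA_integer_,
    unreliable = FALSE, testable = FALSE, reason = NULL,
    reps = reps, seed = seed, pairing_mode = pairing_mode,
    activity_method = activity_method
  ), class = "interval_test")

  if (!length(obs)) {
    res$reason <- "no observed leader-to-follower interval at any station"
    return(res)
  }
  res$observed_median_hours <- stats::median(obs)

  nd <- null_distribution(contacts, leader, follower, dataset, reps, seed,
                          pairing_mode, max_lag_hours, activity_method, kappa)
  res$null_medians <- nd$null_medians
  res$n_invalid_replicates <- nd$n_invalid_replicates
  res$unreliable <- nd$unreliable
  if (!length(nd$null_medians)) {
    res$reason <- "no valid null replicate"
    return(res)
  }

  nm <- nd$null_medians
  res$Q <- (sum(nm > res$observed_median_hours) +
              0.5 * sum(nm == res$observed_median_hours)) / length(nm)
  res$p_two_sided <- interval_p_value(res$Q)
  res$pct_difference <- 100 * (stats::median(nm) - res$observed_median_hours) /
    stats::median(nm)
  res$band_95 <- stats::quantile(nm, c(0.025, 0.975), names = FALSE)
  res$testable <- TRUE
  res
}

#' @export
print.interval_test <- function(x, ...) {
  cat(sprintf("Time-interval test: %s (leader) -> %s (follower)\n",
              x$leader, x$follower))
  if (!x$testable) {
    cat("  untestable:", x$reason %||% "unknown reason", "\n")
    return(invisible(x))
  }
  p_txt <- if (x$p_two_sided == 0) sprintf("< %.3g", 1 / x$reps)
           else sprintf("%.3f", x$p_two_sided)
  cat(sprintf("  observed median interval: %.2f h over %d intervals\n",
              x$observed_median_hours, x$n_intervals_observed))
  cat(sprintf("  null median: %.2f h (95%% band %.2f-%.2f h; %d replicates, %d invalid)\n",
              stats::median(x$null_medians), x$band_95[1], x$band_95[2],
              length(x$null_medians), x$n_invalid_replicates))
  dir <- if (x$pct_difference > 0) "shorter (attraction direction)"
         else "longer (avoidance direction)"
  cat(sprintf("  observed %.1f%% %s than expected; Q = %.3f, two-sided p %s\n",
              abs(x$pct_difference), dir, x$Q, p_txt))
  if (x$unreliable)
    cat("  warning: > 20% of null replicates produced no interval; unreliable\n")
  invisible(x)
}

#' @export
plot.interval_test <- function(x, ...) {
  if (!x$testable) stop_ctti("untestable pair: nothing to plot")
  graphics::hist(x$null_medians, breaks = 30, col = "grey80", border = "grey50",
                 main = sprintf("%s -> %s", x$leader, x$follower),
                 xlab = "median leader-to-follower interval (h)", ...)
  graphics::abline(v = x$observed_median_hours, col = "red", lwd = 2)
  graphics::abline(v = stats::median(x$null_medians), col = "black", lwd = 2)
  graphics::abline(v = x$band_95, lty = 2)
  invisible(x)
}

#' Time-interval tests for every directed species pair
#'
#' Runs [interval_test()] for each ordered pair of the given species (k
#' species give k*(k-1) directed pairs; the study's four ungulates give 12).
#' Each pair draws from its own deterministically derived RNG substream, so
#' any one pair's result is identical whether run alone or as part of the
#' full set.
#'
#' @inheritParams interval_test
#' @param species character vector of species; defaults to all non-human
#'   species in the contacts.
#' @return An `interval_test_set`: named list of `interval_test` objects
#'   (`"leader->follower"`), with `print` and `as.data.frame` methods.
#' @export
run_all_pairs <- function(contacts, dataset, species = NULL,
                          reps = 1000, seed = 1,
                          pairing_mode = c("most_recent", "first_after_leader"),
                          max_lag_hours = Inf,
                          activity_method = c("empirical", "vonmises"),
                          kappa = 50) {
  pairing_mode <- match.arg(pairing_mode)
  activity_method <- match.arg(activity_method)
  if (is.null(species))
    species <- setdiff(sort(unique(contacts$species)), "human")
  species <- canonical_label(species)
  pairs <- expand.grid(follower = species, leader = species,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$leader != pairs$follower, c("leader", "follower")]

  out <- vector("list", nrow(pairs))
  names(out) <- paste0(pairs$leader, "->", pairs$follower)
  for (i in seq_len(nrow(pairs))) {
    out[[i]] <- interval_test(contacts, pairs$leader[i], pairs$follower[i],
                              dataset, reps, seed, pairing_mode,
                              max_lag_hours, activity_method, kappa)
  }
  structure(out, class = "interval_test_set")
}

#' @export
as.data.frame.interval_test_set <- function(x, ...) {
  do.call(rbind, lapply(unname(x), function(r) data.frame(
    leader = r$leader, follower = r$follower,
    n_intervals = r$n_intervals_observed,
    observed_median_hours = r$observed_median_hours,
    null_median_hours = if (length(r$null_medians))
      stats::median(r$null_medians) else NA_real_,
    pct_difference = r$pct_difference,
    Q = r$Q, p_two_sided = r$p_two_sided,
    band_lo = r$band_95[1], band_hi = r$band_95[2],
    n_invalid_replicates = r$n_invalid_replicates,
    testable = r$testable, unreliable = r$unreliable,
    stringsAsFactors = FALSE
  )))
}

#' @export
print.interval_test_set <- function(x, ...) {
  cat(sprintf("Time-interval tests for %d directed pairs\n", length(x)))
  df <- as.data.frame(x)
  df$observed_median_hours <- round(df$observed_median_hours, 2)
  df$null_median_hours <- round(df$null_median_hours, 2)
  df$pct_difference <- round(df$pct_difference, 1)
  df$band_lo <- df$band_hi <- NULL
  print.data.frame(df, row.names = FALSE)
  cat("note: p-values are unadjusted across pairs (no multiplicity correction applied).\n")
  invisible(x)
}
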