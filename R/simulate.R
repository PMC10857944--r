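#' Build a simulation configuration
#'
#' Assembles and validates the configuration of the synthetic camera-trap
#' survey generator. A survey is defined by a station layout (stations per
#' land-cover class, deployment length, staggered start dates), a set of
#' species each with a base log detection rate (log contacts per trap-day at
#' the reference clearfell), per-land-cover log-rate offsets, a negative
#' binomial dispersion `theta`, and a diel activity profile (uniform or a
#' mixture of one or two wrapped von Mises bumps); a human disturbance
#' process with its own diel profile; and an optional list of directed
#' attraction rules, each converting a proportion `pi` of the follower's
#' events into events at an exponential lag (mean `tau_hours`) after a
#' randomly chosen leader event at the same station.
#'
#' @param n_stations named integer vector: stations per land-cover class.
#' @param deployment_days deployment length per station, days.
#' @param start_time first deployment start (ISO-8601 string or POSIXct);
#'   stations start staggered over 5 consecutive days, as field deployments
#'   typically are.
#' @param species named list; each element a list with `base_log_rate`,
#'   `landcover_offsets` (named numeric over the six classes, reference 0),
#'   `theta` (> 0), `diel` (see [diel_profile()]).
#' @param human list with `rate` (contacts per trap-day), `theta`, `diel`.
#' @param attraction list of rules: each a list with `leader`, `follower`,
#'   `pi` in `[0, 1]`, `tau_hours` > 0.
#' @param bursts logical; expand each contact-level event into a short burst
#'   of 1-5 images within 2 minutes, so the independence filter has raw
#'   image sequences to collapse (default `TRUE`).
#' @param seed default master seed used when [simulate_survey()] is called
#'   without one.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_stations = c(clearfell = 2, coniferous_plantation = 8,
                                      grassland = 8, heathland_shrubland = 6,
                                      wetland = 5, woodland = 10),
                       deployment_days = 28,
                       start_time = "2022-05-04T12:00:00",
                       species = default_species_config(n_stations),
                       human = list(rate = 0.30, theta = 0.5,
                                    diel = diel_profile(13, 2)),
                       attraction = list(),
                       bursts = TRUE,
                       seed = 1) {
  if (!all(names(n_stations) %in% land_cover_classes))
    stop_ctti("n_stations must be named by land-cover class")
  stopifnot(all(n_stations >= 0), deployment_days > 0)
  for (nm in names(species)) {
    sp <- species[[nm]]
    stopifnot(is.numeric(sp$base_log_rate), sp$theta > 0)
    if (!all(land_cover_classes %in% names(sp$landcover_offsets)))
      stop_ctti("landcover_offsets of ", nm, " must cover all six classes")
    validate_diel(sp$diel)
  }
  stopifnot(human$rate >= 0, human$theta > 0)
  validate_diel(human$diel)
  for (rule in attraction) {
    if (!rule$leader %in% names(species) || !rule$follower %in% names(species))
      stop_ctti("attraction rule references unknown species: ",
                rule$leader, " -> ", rule$follower)
    stopifnot(rule$pi >= 0, rule$pi <= 1, rule$tau_hours > 0)
  }
  structure(list(
    n_stations = n_stations, deployment_days = deployment_days,
    start_time = format_timestamp(parse_timestamp(start_time)),
    species = species, human = human, attraction = attraction,
    bursts = isTRUE(bursts), seed = seed
  ), class = "sim_config")
}

#' Diel activity profile specification
#'
#' @param peaks_hours peak clock times (hours, 0-24) of 1-2 activity bumps;
#'   `NULL` for a uniform profile.
#' @param kappa von Mises concentration of each bump (recycled).
#' @param weights mixture weights (must sum to 1; recycled uniform).
#' @return A list describing the profile.
#' @export
diel_profile <- function(peaks_hours = NULL, kappa = 2, weights = NULL) {
  if (is.null(peaks_hours)) return(list(type = "uniform"))
  k <- length(peaks_hours)
  kappa <- rep_len(kappa, k)
  if (is.null(weights)) weights <- rep(1 / k, k)
  list(type = "mixture", peaks_hours = peaks_hours, kappa = kappa,
       weights = weights)
}

validate_diel <- function(diel) {
  if (identical(diel$type, "uniform")) return(invisible(TRUE))
  stopifnot(identical(diel$type, "mixture"),
            length(diel$peaks_hours) >= 1,
            all(diel$kappa > 0),
            abs(sum(diel$weights) - 1) < 1e-8)
  invisible(TRUE)
}

# default four-ungulate community: offsets shaped like the land-cover
# preferences of a Highland ungulate assemblage, base rates calibrated so the
# station-weighted mean detection rates are 0.60 / 0.12 / 0.04 / 0.11
# contacts per day; theta back-calculated from per-station rate mean/SD
default_species_config <- function(n_stations) {
  offs <- list(
    sika_deer = c(clearfell = 0, coniferous_plantation = 2.5, grassland = 3.3,
                  heathland_shrubland = 1.6, wetland = 1.6, woodland = 2.6),
    roe_deer  = c(clearfell = 0, coniferous_plantation = 1.2, grassland = 1.1,
                  heathland_shrubland = 0.3, wetland = 0.9, woodland = 0.0),
    red_deer  = c(clearfell = 0, coniferous_plantation = 0.45, grassland = 0.32,
                  heathland_shrubland = 0.33, wetland = 1.33, woodland = -0.15),
    wild_boar = c(clearfell = 0, coniferous_plantation = 0.9, grassland = 5.1,
                  heathland_shrubland = 2.6, wetland = -6.0, woodland = 4.4)
  )
  target <- c(sika_deer = 0.60, roe_deer = 0.12, red_deer = 0.04,
              wild_boar = 0.11)
  theta <- c(sika_deer = 0.45, roe_deer = 0.65, red_deer = 0.75,
             wild_boar = 0.35)
  diel <- list(
    sika_deer = diel_profile(c(5.5, 20), kappa = 2),
    roe_deer  = diel_profile(c(5.5, 19.5), kappa = 2),
    red_deer  = diel_profile(c(6, 20.5), kappa = 1.5),
    wild_boar = diel_profile(1, kappa = 1.5)
  )
  w <- n_stations[land_cover_classes]
  w[is.na(w)] <- 0
  lapply(stats::setNames(nm = names(offs)), function(s) {
    o <- offs[[s]][land_cover_classes]
    base <- log(target[[s]]) - log(sum(w * exp(o)) / sum(w))
    list(base_log_rate = base, landcover_offsets = offs[[s]],
         theta = theta[[s]], diel = diel[[s]])
  })
}

#' Survey configuration emulating the published study regime
#'
#' Returns a [sim_config()] with 39 stations split 2 clearfell / 8 coniferous
#' plantation / 8 grassland / 6 heathland-shrubland / 5 wetland / 10 woodland,
#' 28-day deployments, the four ungulates at site-wide mean detection rates of
#' about 0.60, 0.12, 0.04 and 0.11 contacts per day with crepuscular deer and
#' nocturnal boar diel profiles, diurnal humans at 0.30 contacts per day, and
#' (optionally) one injected attraction rule: roe deer leader to sika deer
#' follower with conversion proportion 0.4 and mean lag 2 h.
#'
#' @param seed master seed stored in the config.
#' @param attraction include the roe-to-sika attraction rule (default `TRUE`).
#' @return A `sim_config`.
#' @export
preset_paper_like <- function(seed = 1, attraction = TRUE) {
  rules <- if (attraction)
    list(list(leader = "roe_deer", follower = "sika_deer",
              pi = 0.4, tau_hours = 2))
  else list()
  sim_config(attraction = rules, seed = seed)
}

# draw n clock times (seconds) from a diel profile
rdiel <- function(n, diel) {
  if (n == 0) return(numeric(0))
  if (identical(diel$type, "uniform")) return(stats::runif(n, 0, 86400))
  comp <- sample.int(length(diel$weights), n, replace = TRUE,
                     prob = diel$weights)
  ang <- numeric(n)
  for (j in seq_along(diel$weights)) {
    idx <- which(comp == j)
    if (length(idx)) ang[idx] <- rvonmises(length(idx), 0, diel$kappa[j])
  }
  (diel$peaks_hours[comp] * 3600 + ang * 86400 / (2 * pi)) %% 86400
}

# place n events uniformly over a station's active dates with diel times,
# rejection-sampled into the closed-open deployment window
place_event_times <- function(n, start_abs, end_abs, diel) {
  if (n == 0) return(numeric(0))
  d0 <- floor(start_abs / 86400)
  d1 <- floor((end_abs - 1e-6) / 86400)
  n_dates <- d1 - d0 + 1
  t <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    day <- d0 + floor(stats::runif(length(todo)) * n_dates)
    t[todo] <- day * 86400 + rdiel(length(todo), diel)
    bad <- t[todo] < start_abs | t[todo] >= end_abs
    todo <- todo[bad]
  }
  t
}

#' Simulate a camera-trap survey
#'
#' Generates one synthetic survey under a [sim_config()]: per station and
#' species, a total event count is drawn from a negative binomial with mean
#' `duration_days * exp(base_log_rate + landcover_offset)` and size `theta`;
#' events are placed on uniformly drawn active dates at diel-profile times
#' (rejection-sampled into the deployment window). Attraction rules then
#' convert a `pi` fraction of the follower's events, at stations where the
#' leader occurs, into events at an exponential lag after a randomly chosen
#' leader event. Human events are generated the same way from the human
#' profile. If `bursts` is on, each contact-level event is expanded into a
#' burst of 1-5 images within 2 minutes so the independence filter has work
#' to do.
#'
#' @param config a `sim_config`.
#' @param seed master seed; defaults to `config$seed`. A fixed seed
#'   reproduces the survey exactly.
#' @return A list of class `simulated_survey` with elements `dataset` (a
#'   [survey_dataset()]) and `truth` (the realized configuration, per-station
#'   expected counts, the contact-level event table with an `injected` flag
#'   marking attraction-converted events, and the seed).
#' @export
simulate_survey <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)

  lc <- rep(names(config$n_stations), config$n_stations)
  n_st <- length(lc)
  station <- sprintf("st%02d", seq_len(n_st))
  start0 <- as.numeric(parse_timestamp(config$start_time))
  stagger <- (seq_len(n_st) - 1) %% 5
  start_abs <- start0 + stagger * 86400
  end_abs <- start_abs + config$deployment_days * 86400

  dep <- data.frame(
    station_id = station,
    start = as.POSIXct(start_abs, tz = "UTC", origin = "1970-01-01"),
    end = as.POSIXct(end_abs, tz = "UTC", origin = "1970-01-01"),
    land_cover = lc, stringsAsFactors = FALSE
  )

  ev_station <- character(0); ev_species <- character(0)
  ev_time <- numeric(0); ev_injected <- logical(0)
  expected <- list()

  gen_species <- function(name, base_log_rate, offsets, theta, diel) {
    mu <- config$deployment_days * exp(base_log_rate + offsets[lc])
    n <- stats::rnbinom(n_st, size = theta, mu = mu)
    times <- unlist(lapply(seq_len(n_st), function(i)
      place_event_times(n[i], start_abs[i], end_abs[i], diel)), use.names = FALSE)
    list(station = rep(station, n), time = times %||% numeric(0), mu = mu)
  }

  for (sp in names(config$species)) {
    cf <- config$species[[sp]]
    g <- gen_species(sp, cf$base_log_rate, cf$landcover_offsets, cf$theta,
                     cf$diel)
    ev_station <- c(ev_station, g$station)
    ev_species <- c(ev_species, rep(sp, length(g$time)))
    ev_time <- c(ev_time, g$time)
    ev_injected <- c(ev_injected, rep(FALSE, length(g$time)))
    expected[[sp]] <- g$mu
  }
  if (config$human$rate > 0) {
    hg <- gen_species("human", log(config$human$rate),
                      stats::setNames(rep(0, 6), land_cover_classes),
                      config$human$theta, config$human$diel)
    ev_station <- c(ev_station, hg$station)
    ev_species <- c(ev_species, rep("human", length(hg$time)))
    ev_time <- c(ev_time, hg$time)
    ev_injected <- c(ev_injected, rep(FALSE, length(hg$time)))
  }

  # attraction: re-time a pi fraction of follower events to sit at an
  # exponential lag after a random leader event at the same station
  st_index <- match(ev_station, station)
  for (rule in config$attraction) {
    lead_idx <- which(ev_species == rule$leader)
    fol_idx <- which(ev_species == rule$follower)
    if (!length(lead_idx) || !length(fol_idx)) next
    leaders_by_st <- split(ev_time[lead_idx], st_index[lead_idx])
    has_leader <- st_index[fol_idx] %in% as.integer(names(leaders_by_st))
    sel <- fol_idx[has_leader & stats::runif(length(fol_idx)) < rule$pi]
    for (i in sel) {
      s <- st_index[i]
      pool <- leaders_by_st[[as.character(s)]]
      repeat {
        t_new <- pool[sample.int(length(pool), 1)] +
          stats::rexp(1, rate = 1 / (rule$tau_hours * 3600))
        if (t_new >= start_abs[s] && t_new < end_abs[s]) break
      }
      ev_time[i] <- t_new
      ev_injected[i] <- TRUE
    }
  }

  # burst expansion: each contact-level event becomes 1-5 images within 2 min
  if (config$bursts && length(ev_time)) {
    k <- sample.int(5, length(ev_time), replace = TRUE)
    extra <- k - 1L
    rep_idx <- rep(seq_along(ev_time), extra)
    off <- stats::runif(length(rep_idx), 1, 120)
    img_time <- c(ev_time, pmin(ev_time[rep_idx] + off,
                                end_abs[st_index[rep_idx]] - 1))
    img_station <- c(ev_station, ev_station[rep_idx])
    img_species <- c(ev_species, ev_species[rep_idx])
  } else {
    img_time <- ev_time; img_station <- ev_station; img_species <- ev_species
  }

  det <- data.frame(
    station_id = img_station, species = img_species,
    timestamp = as.POSIXct(floor(img_time), tz = "UTC", origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
  dataset <- survey_dataset(dep, det)

  truth <- list(
    config = config, seed = seed,
    expected_counts = data.frame(
      station_id = rep(station, length(expected)),
      species = rep(names(expected), each = n_st),
      expected = unlist(expected, use.names = FALSE),
      stringsAsFactors = FALSE
    ),
    events = data.frame(
      station_id = ev_station, species = ev_species,
      timestamp = as.POSIXct(floor(ev_time), tz = "UTC", origin = "1970-01-01"),
      injected = ev_injected, stringsAsFactors = FALSE
    )
  )
  structure(list(dataset = dataset, truth = truth),
            class = "simulated_survey")
}

#' @export
print.simulated_survey <- function(x, ...) {
  cat("Simulated camera-trap survey (seed ", x$truth$seed, ")\n", sep = "")
  print(x$dataset)
  inj <- sum(x$truth$events$injected)
  if (inj) cat(sprintf("  injected attraction events: %d\n", inj))
  invisible(x)
}

#' Write a simulated survey to a directory
#'
#' Writes `detections.csv`, `deployments.csv` and `ground_truth.json`
#' (realized configuration, seed, expected per-station counts, injected-event
#' count) for a simulated survey.
#'
#' @param sim a `simulated_survey` from [simulate_survey()].
#' @param out_dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_simulated_survey <- function(sim, out_dir) {
  stopifnot(inherits(sim, "simulated_survey"))
  paths <- write_survey(sim$dataset, out_dir)
  gt <- file.path(out_dir, "ground_truth.json")
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  truth$events <- NULL
  truth$n_injected_events <- sum(sim$truth$events$injected)
  jsonlite::write_json(truth, gt, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, ground_truth = gt))
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `sim_config`.
#' @return `read_sim_config` returns a validated `sim_config`;
#'   `write_sim_config` invisibly returns `path`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  # named numeric vectors must become maps, or YAML drops the names
  x$n_stations <- as.list(x$n_stations)
  x$species <- lapply(x$species, function(sp) {
    sp$landcover_offsets <- as.list(sp$landcover_offsets)
    sp
  })
  writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$n_stations <- unlist(raw$n_stations)
  raw$species <- lapply(raw$species, function(sp) {
    sp$landcover_offsets <- unlist(sp$landcover_offsets)
    sp
  })
  do.call(sim_config, raw)
}
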