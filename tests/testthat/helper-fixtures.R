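# fixtures built in code and independent brute-force oracles

# a survey dataset from event times given in minutes after each station's start
ds_from_minutes <- function(events, n_stations = 2, days = 28,
                            land_cover = NULL,
                            start = "2022-05-04T00:00:00") {
  ids <- sprintf("st%02d", seq_len(n_stations))
  if (is.null(land_cover))
    land_cover <- rep_len(land_cover_classes, n_stations)
  t0 <- as.POSIXct(sub("T", " ", start), tz = "UTC")
  dep <- data.frame(station_id = ids, start = t0,
                    end = t0 + rep_len(days, n_stations) * 86400,
                    land_cover = land_cover)
  n <- length(events$minutes)
  det <- data.frame(station_id = rep_len(events$station_id, n),
                    species = rep_len(events$species, n),
                    timestamp = t0 + events$minutes * 60)
  survey_dataset(dep, det)
}

contacts_from_minutes <- function(events, ...) {
  ds <- ds_from_minutes(events, ...)
  list(dataset = ds, contacts = filter_independent(ds, window_minutes = 0))
}

# brute-force independence filter over one (station, species) stream
brute_filter_stream <- function(minutes, window, mode = "rolling") {
  minutes <- sort(minutes)
  if (!length(minutes)) return(numeric(0))
  keep <- minutes[1]
  anchor <- minutes[1]  # last detection (rolling) or contact opener (from_contact)
  for (t in minutes[-1]) {
    ref <- if (mode == "rolling") anchor else keep[length(keep)]
    if (t - ref > window) keep <- c(keep, t)
    anchor <- t
  }
  keep
}

# brute-force leader->follower intervals (hours), quadratic scan per station
brute_intervals <- function(l_min, f_min, pairing = "most_recent") {
  out <- numeric(0)
  used <- rep(FALSE, length(l_min))
  for (tf in sort(f_min)) {
    prev <- which(l_min <= tf)
    if (!length(prev)) next
    j <- prev[which.max(l_min[prev])]
    if (pairing == "first_after_leader") {
      if (used[j]) next
      used[j] <- TRUE
    }
    out <- c(out, (tf - l_min[j]) / 60)
  }
  out
}

# random raw detection stream for oracle checks: minutes on a 28-day window
random_stream <- function(n, span_minutes = 28 * 24 * 60) {
  sort(round(runif(n, 0, span_minutes - 1), 0))
}
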