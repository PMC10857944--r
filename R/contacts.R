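#' Collapse raw detections into independent contacts
#'
#' Applies the independence rule used throughout camera-trap work: within each
#' (station, species) stream, the first image of a sequence opens a contact,
#' and a later image opens a new contact only when it is separated from the
#' sequence by more than `window_minutes`. Two readings of "separated" are
#' supported:
#'
#' * `"rolling"` (default): the gap is measured from the immediately preceding
#'   detection of that species at that station, so a sequence stays unbroken
#'   while consecutive gaps remain at or below the window even if it spans
#'   more than the window in total.
#' * `"from_contact"`: the gap is measured from the opening detection of the
#'   current contact.
#'
#' A gap of exactly `window_minutes` merges ("greater than" is strict). A
#' window of 0 returns every detection as its own contact.
#'
#' @param dataset a [survey_dataset()].
#' @param window_minutes independence window in minutes (default 30).
#' @param independence_mode `"rolling"` or `"from_contact"`.
#' @return A `contact_table`: data frame `station_id,species,timestamp`
#'   (timestamp of the opening detection of each contact), carrying the
#'   window and mode as attributes.
#' @export
filter_independent <- function(dataset, window_minutes = 30,
                               independence_mode = c("rolling", "from_contact")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  independence_mode <- match.arg(independence_mode)
  if (!is.numeric(window_minutes) || length(window_minutes) != 1 ||
      is.na(window_minutes) || window_minutes < 0)
    stop_ctti("window_minutes must be a single non-negative number")

  det <- dataset$detections
  if (!nrow(det)) return(new_contact_table(det, window_minutes, independence_mode))

  # detections are stored ordered by (station, species, time)
  grp <- paste(det$station_id, det$species, sep = "\r")
  t <- as.numeric(det$timestamp)
  w <- window_minutes * 60

  if (independence_mode == "rolling") {
    gap <- c(Inf, diff(t))
    new_grp <- c(TRUE, grp[-1] != grp[-length(grp)])
    opens <- new_grp | gap > w
  } else {
    opens <- logical(nrow(det))
    start <- 1L
    for (i in seq_len(nrow(det))) {
      if (i == 1L || grp[i] != grp[i - 1L]) {
        opens[i] <- TRUE; start <- i
      } else if (t[i] - t[start] > w) {
        opens[i] <- TRUE; start <- i
      }
    }
  }
  new_contact_table(det[opens, , drop = FALSE], window_minutes, independence_mode)
}

new_contact_table <- function(df, window_minutes, independence_mode) {
  df <- df[, c("station_id", "species", "timestamp"), drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("contact_table", "data.frame"),
            window_minutes = window_minutes,
            independence_mode = independence_mode)
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("Independent contacts (%d rows; window %g min, %s mode)\n",
              nrow(x), attr(x, "window_minutes"), attr(x, "independence_mode")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Days of survey effort per independent contact
#'
#' The average number of trap-days needed to photograph a species once:
#' total trap-days divided by total contacts.
#'
#' @param trap_days total survey effort in trap-days.
#' @param n_contacts total independent contacts of the species.
#' @return Days per contact; `NA` when `n_contacts` is zero.
#' @export
days_per_contact <- function(trap_days, n_contacts) {
  stopifnot(is.numeric(trap_days), is.numeric(n_contacts), n_contacts >= 0)
  ifelse(n_contacts > 0, trap_days / n_contacts, NA_real_)
}

#' Per-species survey summary
#'
#' Computes, for one species, the standard camera-trap summary statistics:
#' naive occupancy (percentage of stations with recorded effort at which the
#' species was contacted at least once, with no detectability correction),
#' total independent contacts, the mean and SD across stations of the
#' per-station detection rate (contacts per trap-day), and days per contact.
#'
#' @param contacts a `contact_table` from [filter_independent()].
#' @param dataset the [survey_dataset()] the contacts came from.
#' @param species canonical species label (e.g. `"sika_deer"`).
#' @return A one-row data frame with columns `species`,
#'   `naive_occupancy_pct`, `total_contacts`, `mean_detection_rate`,
#'   `sd_detection_rate`, `days_per_contact`.
#' @export
summarize_species <- function(contacts, dataset, species) {
  stopifnot(inherits(contacts, "contact_table"), inherits(dataset, "survey_dataset"))
  species <- canonical_label(species)
  if (length(species) != 1 || !nzchar(species))
    stop_ctti("species must be a single non-empty label")

  dep <- dataset$deployments
  eff <- dep$duration_days > 0
  dep <- dep[eff, , drop = FALSE]

  cs <- contacts[contacts$species == species, , drop = FALSE]
  n_by_station <- table(factor(cs$station_id, levels = dep$station_id))
  counts <- as.numeric(n_by_station)
  rates <- counts / dep$duration_days
  total <- sum(counts)

  data.frame(
    species = species,
    naive_occupancy_pct = 100 * mean(counts > 0),
    total_contacts = total,
    mean_detection_rate = mean(rates),
    sd_detection_rate = stats::sd(rates),
    days_per_contact = days_per_contact(sum(dep$duration_days), total),
    stringsAsFactors = FALSE
  )
}

#' Survey summary table for several species
#'
#' @param contacts a `contact_table`.
#' @param dataset the source [survey_dataset()].
#' @param species character vector of species; defaults to every non-human
#'   species present in the contacts.
#' @return Data frame with one [summarize_species()] row per species.
#' @export
species_summary_table <- function(contacts, dataset, species = NULL) {
  if (is.null(species))
    species <- setdiff(sort(unique(contacts$species)), "human")
  do.call(rbind, lapply(species, function(s) summarize_species(contacts, dataset, s)))
}

#' Human detection rate per station
#'
#' Human contacts per trap-day at each station, the human-disturbance
#' covariate of the detection-rate models. Stations with no human contacts
#' get rate 0.
#'
#' @param contacts a `contact_table` built with the same independence window
#'   as the species contacts.
#' @param dataset the source [survey_dataset()].
#' @return Data frame `station_id,human_rate`, one row per station.
#' @export
human_detection_rates <- function(contacts, dataset) {
  stopifnot(inherits(contacts, "contact_table"), inherits(dataset, "survey_dataset"))
  dep <- dataset$deployments
  h <- contacts[contacts$species == "human", , drop = FALSE]
  n <- table(factor(h$station_id, levels = dep$station_id))
  data.frame(station_id = dep$station_id,
             human_rate = as.numeric(n) / dep$duration_days,
             stringsAsFactors = FALSE)
}

#' Share of contacts excluded as unidentifiable
#'
#' Percentage of all (identified + unidentified) ungulate contacts that could
#' not be identified to species and were excluded upstream.
#'
#' @param n_unidentified number of unidentifiable contacts.
#' @param contacts optionally, a `contact_table` from which identified
#'   ungulate totals are taken (all non-human species).
#' @param n_identified alternatively, a numeric vector of identified contact
#'   totals (e.g. the per-species totals of a published summary table).
#' @return Percentage in `[0, 100]`; `NA` when both counts are zero.
#' @export
unidentified_share <- function(n_unidentified, contacts = NULL, n_identified = NULL) {
  stopifnot(is.numeric(n_unidentified), length(n_unidentified) == 1,
            n_unidentified >= 0)
  if (is.null(n_identified)) {
    if (is.null(contacts))
      stop_ctti("supply either contacts or n_identified")
    n_identified <- sum(contacts$species != "human")
  }
  tot <- n_unidentified + sum(n_identified)
  if (tot == 0) return(NA_real_)
  100 * n_unidentified / tot
}
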