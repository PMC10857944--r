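#' Assemble and validate a camera-trap survey dataset
#'
#' Bundles a deployment table (one row per camera station: active interval
#' plus land-cover class) with a detection table (one time-stamped species
#' record per row) into a validated `survey_dataset`. Validation enforces the
#' survey data model: unique stations, positive deployment durations, land
#' cover drawn from [land_cover_classes], every detection at a known station,
#' and every detection inside its station's active interval. The deployment
#' interval is treated as closed-open `[start, end)`, so a detection stamped
#' exactly at `end` is rejected.
#'
#' Detections falling outside their station's deployment window are not
#' silently dropped: they are removed from the dataset and collected, with a
#' `reason` column, in the `rejects` attribute (see [survey_rejects()]).
#'
#' @param deployments data frame with columns `station_id`, `start`, `end`
#'   (`POSIXct` or ISO-8601 strings) and `land_cover`.
#' @param detections data frame with columns `station_id`, `species` and
#'   `timestamp`. Species labels are case-folded to lowercase snake_case
#'   (`"Sika deer"` becomes `"sika_deer"`).
#' @return A `survey_dataset`: a list with elements `deployments` (gains a
#'   derived `duration_days` column) and `detections` (time-ordered), plus a
#'   `rejects` attribute.
#' @seealso [read_survey()], [write_survey()], [trap_days()]
#' @export
survey_dataset <- function(deployments, detections) {
  dep <- as.data.frame(deployments)
  det <- as.data.frame(detections)

  need_dep <- c("station_id", "start", "end", "land_cover")
  if (!all(need_dep %in% names(dep)))
    stop_ctti("deployments must have columns: ", paste(need_dep, collapse = ", "))
  need_det <- c("station_id", "species", "timestamp")
  if (!all(need_det %in% names(det)))
    stop_ctti("detections must have columns: ", paste(need_det, collapse = ", "))

  dep$station_id <- as.character(dep$station_id)
  if (anyDuplicated(dep$station_id))
    stop_ctti("duplicated station_id in deployments; one deployment row per station")

  if (!inherits(dep$start, "POSIXct")) dep$start <- parse_timestamp(dep$start)
  if (!inherits(dep$end, "POSIXct"))   dep$end   <- parse_timestamp(dep$end)
  if (anyNA(dep$start) || anyNA(dep$end))
    stop_ctti("unparseable start/end timestamp in deployments")

  dep$land_cover <- canonical_label(dep$land_cover)
  bad_lc <- setdiff(unique(dep$land_cover), land_cover_classes)
  if (length(bad_lc))
    stop_ctti("unknown land-cover label(s): ", paste(bad_lc, collapse = ", "),
              "; allowed: ", paste(land_cover_classes, collapse = ", "))

  if (any(dep$end <= dep$start))
    stop_ctti("deployment end must be after start for every station")
  dep$duration_days <- as.numeric(difftime(dep$end, dep$start, units = "days"))

  det$station_id <- as.character(det$station_id)
  det$species <- canonical_label(det$species)
  if (nrow(det) && any(!nzchar(det$species)))
    stop_ctti("empty species label in detections")
  if (!inherits(det$timestamp, "POSIXct")) {
    ts <- parse_timestamp(det$timestamp)
    if (anyNA(ts)) {
      bad <- which(is.na(ts))
      stop_ctti("unparseable detection timestamp at row(s): ",
                paste(utils::head(bad, 5), collapse = ", "))
    }
    det$timestamp <- ts
  }

  unknown <- setdiff(unique(det$station_id), dep$station_id)
  if (length(unknown))
    stop_ctti("detection(s) at unknown station(s): ",
              paste(unknown, collapse = ", "))

  # closed-open window check: reject t < start or t >= end
  i <- match(det$station_id, dep$station_id)
  ok <- rep(TRUE, nrow(det))
  reason <- character(nrow(det))
  if (nrow(det)) {
    before <- det$timestamp < dep$start[i]
    after  <- det$timestamp >= dep$end[i]
    ok <- !(before | after)
    reason[before] <- "before deployment start"
    reason[after]  <- "at or after deployment end"
  }
  rejects <- det[!ok, need_det, drop = FALSE]
  if (nrow(rejects)) rejects$reason <- reason[!ok] else rejects$reason <- character(0)
  rownames(rejects) <- NULL

  det <- det[ok, need_det, drop = FALSE]
  det <- det[order(det$station_id, det$species, det$timestamp), , drop = FALSE]
  rownames(det) <- NULL

  out <- structure(
    list(deployments = dep[, c(need_dep, "duration_days")], detections = det),
    class = "survey_dataset"
  )
  attr(out, "rejects") <- rejects
  out
}

#' Detections rejected during dataset validation
#'
#' @param dataset a [survey_dataset()].
#' @return Data frame mirroring the detection table plus a `reason` column.
#' @export
survey_rejects <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  attr(dataset, "rejects")
}

#' Total survey effort in trap-days
#'
#' One trap-day is one camera operating for one day; total effort is the sum
#' of deployment durations and is the denominator of detection rates and the
#' offset of the detection-rate models.
#'
#' @param dataset a [survey_dataset()].
#' @return A single number of trap-days.
#' @export
trap_days <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  sum(dataset$deployments$duration_days)
}

#' Read a survey from delimited text files
#'
#' Reads `detections.csv` (`station_id,species,timestamp`) and
#' `deployments.csv` (`station_id,start,end,land_cover`), with ISO-8601
#' timestamps, and returns a validated [survey_dataset()]. Malformed input
#' (missing columns, unparseable timestamps, unknown land-cover labels,
#' detections at unknown stations) is a hard error; detections outside their
#' deployment window go to the rejects report instead.
#'
#' @param detections_path,deployments_path paths to the two CSV files.
#' @return A [survey_dataset()].
#' @export
read_survey <- function(detections_path, deployments_path) {
  for (p in c(detections_path, deployments_path))
    if (!file.exists(p)) stop_ctti("file not found: ", p)
  det <- utils::read.csv(detections_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  dep <- utils::read.csv(deployments_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  survey_dataset(dep, det)
}

#' Write a survey back to delimited text files
#'
#' Serializes a dataset to `detections.csv` and `deployments.csv` (ISO-8601
#' timestamps) such that [read_survey()] round-trips it exactly. If any
#' rejected detections are attached, a `rejects.csv` is written alongside.
#'
#' @param dataset a [survey_dataset()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_survey <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop_ctti("cannot create directory: ", out_dir)
  }
  det <- dataset$detections
  det$timestamp <- format_timestamp(det$timestamp)
  dep <- dataset$deployments[, c("station_id", "start", "end", "land_cover")]
  dep$start <- format_timestamp(dep$start)
  dep$end <- format_timestamp(dep$end)

  paths <- c(detections = file.path(out_dir, "detections.csv"),
             deployments = file.path(out_dir, "deployments.csv"))
  utils::write.csv(det, paths[["detections"]], row.names = FALSE)
  utils::write.csv(dep, paths[["deployments"]], row.names = FALSE)

  rej <- survey_rejects(dataset)
  if (!is.null(rej) && nrow(rej)) {
    rej$timestamp <- format_timestamp(rej$timestamp)
    paths <- c(paths, rejects = file.path(out_dir, "rejects.csv"))
    utils::write.csv(rej, paths[["rejects"]], row.names = FALSE)
  }
  invisible(paths)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Camera-trap survey dataset\n")
  cat(sprintf("  stations:   %d (%.1f trap-days)\n",
              nrow(x$deployments), trap_days(x)))
  sp <- sort(unique(x$detections$species))
  cat(sprintf("  detections: %d across %d species (%s)\n",
              nrow(x$detections), length(sp),
              paste(utils::head(sp, 8), collapse = ", ")))
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej))
    cat(sprintf("  rejects:    %d out-of-window detections (see survey_rejects())\n",
                nrow(rej)))
  invisible(x)
}

#' @export
summary.survey_dataset <- function(object, ...) {
  dep <- object$deployments
  det <- object$detections
  lc <- table(factor(dep$land_cover, levels = land_cover_classes))
  out <- list(
    n_stations = nrow(dep),
    trap_days = trap_days(object),
    land_cover = lc,
    detections_by_species = sort(table(det$species), decreasing = TRUE),
    n_rejects = nrow(attr(object, "rejects") %||% data.frame())
  )
  class(out) <- "summary.survey_dataset"
  out
}

#' @export
print.summary.survey_dataset <- function(x, ...) {
  cat(sprintf("Survey: %d stations, %.1f trap-days, %d rejected detections\n",
              x$n_stations, x$trap_days, x$n_rejects))
  cat("Stations by land cover:\n")
  print(x$land_cover)
  cat("Detections by species:\n")
  print(x$detections_by_species)
  invisible(x)
}
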