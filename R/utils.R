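# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical land-cover classes
#'
#' The six land-cover classes a deployment may carry, in the order used as
#' factor levels throughout the package. `"clearfell"` is the reference level
#' of the detection-rate models.
#'
#' @format A character vector of length 6.
#' @export
land_cover_classes <- c(
  "clearfell", "coniferous_plantation", "grassland",
  "heathland_shrubland", "wetland", "woodland"
)

# case-fold a label to lowercase snake_case ("Sika deer" -> "sika_deer")
canonical_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

# parse ISO-8601-ish timestamps ("2022-05-10T06:42:00" or with a space),
# timezone-naive local civil time stored as UTC so no DST arithmetic occurs
parse_timestamp <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# deterministic small-integer seed stream derived from a master seed;
# kept below 2^31 so set.seed() accepts it on all platforms
derive_seed <- function(master, stream, index = 0L) {
  m <- 2147483629
  s <- (as.numeric(master) %% m)
  s <- (s * 48271 + as.numeric(stream) * 131071 + as.numeric(index) * 7919) %% m
  as.integer(s) + 1L
}

stop_ctti <- function(...) stop(..., call. = FALSE)
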