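# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic numeric formatting for text exports (round-trips doubles).
fmt_num <- function(x, digits = 12) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

# Monday of the first modelled week; all week indices count from here.
week_origin <- function() as.Date("2020-01-06")

#' Weekly time bin of a timestamp
#'
#' Maps a UTC timestamp to its week index `t = 1, 2, ...`, where weeks are
#' Monday-starting and week 1 begins 2020-01-06. Timestamps before the origin
#' get non-positive indices and are dropped by frequency counting.
#'
#' @param time A `POSIXct`/`Date` vector or an ISO-8601 character vector (UTC).
#' @return Integer vector of week indices.
#' @export
#' @examples
#' week_index(as.Date("2020-01-06")) # 1
#' week_index(as.Date("2020-01-13")) # 2
week_index <- function(time) {
  if (is.character(time)) {
    time <- as.POSIXct(time, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%d %H:%M:%S",
                                      "%Y-%m-%d"))
  }
  d <- as.Date(time, tz = "UTC")
  as.integer(floor(as.numeric(d - week_origin()) / 7)) + 1L
}

# timestamp formatter used by all writers (fixed, locale-independent)
fmt_time <- function(time) format(time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)
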