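# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Sub-seeds are hashes of `"master|label1|label2|..."` masked to
#' `[0, 2^31)`. Hashing (rather than `master + offset`) guarantees that
#' adding or removing one consumer never shifts the stream of any other:
#' the per-sample rarefaction draws, for example, are keyed on
#' `(seed, sample_id, replicate)` so subsetting samples leaves the
#' remaining samples' draws untouched.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return a single integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "|")
  bitwAnd(digest::digest2int(key), 0x7FFFFFFFL)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Local wall-clock datetimes: parsed in a fixed zone so no DST arithmetic
# ever applies (single-site study; diurnal analyses need clock time).
GR_TZ <- "UTC"

parse_datetime <- function(x) {
  out <- as.POSIXct(x, tz = GR_TZ,
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(out) && !all(is.na(x) | !nzchar(x))) {
    bad <- x[is.na(out) & !is.na(x) & nzchar(x)]
    if (length(bad))
      stop("unparseable datetime(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

format_datetime <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = GR_TZ)

clock_hour <- function(dt) {
  lt <- as.POSIXlt(dt, tz = GR_TZ)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

midnight_of <- function(dt) {
  as.POSIXct(trunc(as.POSIXlt(min(dt), tz = GR_TZ), "days"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recursive merge of a user config into defaults (names present in `user`
# override; unnamed/absent keys keep defaults).
merge_config <- function(default, user) {
  if (is.null(user)) return(default)
  if (!is.list(default) || !is.list(user)) return(user)
  for (nm in names(user)) {
    default[[nm]] <- if (nm %in% names(default))
      merge_config(default[[nm]], user[[nm]]) else user[[nm]]
  }
  default
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
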