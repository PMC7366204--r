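#' @import data.table
#' @importFrom stats runif rbinom
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize timestamps to canonical naive ISO-8601
#'
#' Accepts `Date`, `POSIXct`, `"YYYY-MM-DD"`, or `"YYYY-MM-DD[ T]HH:MM:SS"`
#' and returns `"YYYY-MM-DDTHH:MM:SS"` strings. The fixed-width form makes
#' lexicographic order equal chronological order, so the store never needs a
#' timezone: timestamps are naive, source-local, as in typical EHR extracts.
#'
#' @param x vector of timestamps.
#' @return character vector in canonical form; `NA` stays `NA`.
#' @export
canon_ts <- function(x) {
  if (inherits(x, "Date")) return(paste0(format(x, "%Y-%m-%d"), "T00:00:00"))
  if (inherits(x, "POSIXt")) return(format(x, "%Y-%m-%dT%H:%M:%S"))
  x <- as.character(x)
  x <- sub(" ", "T", trimws(x), fixed = TRUE)
  date_only <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  x[date_only] <- paste0(x[date_only], "T00:00:00")
  ok <- is.na(x) | grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$", x)
  if (!all(ok)) {
    stop("unparseable timestamp(s): ",
         paste(utils::head(x[!ok], 3L), collapse = ", "), call. = FALSE)
  }
  x
}

# Comparison operators accepted throughout (unicode aliases normalized).
.cf_ops <- c(">", "<", ">=", "<=", "=", "exists")

normalize_op <- function(op) {
  op <- switch(op, "≥" = ">=", "≤" = "<=", "==" = "=", op)
  if (!op %in% .cf_ops) {
    stop("unsupported operator '", op, "'; use one of ",
         paste(.cf_ops, collapse = " "), call. = FALSE)
  }
  op
}

apply_op <- function(values, op, threshold) {
  if (op == "exists") return(rep(TRUE, length(values)))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
    stop("numeric predicate '", op, "' needs a single numeric threshold",
         call. = FALSE)
  }
  switch(op,
    ">"  = values > threshold,
    "<"  = values < threshold,
    ">=" = values >= threshold,
    "<=" = values <= threshold,
    "="  = values == threshold)
}
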