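`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Hashes a stage label together with the master seed so that every stochastic
#' stage of the pipeline draws from its own named stream: adding or reordering
#' stages never shifts another stage's random numbers. The result always fits
#' in a 32-bit integer.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the stream (e.g. `"cohort/control/3"`).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(abs(seed) %% 2147483647)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) && x >= min
}

assert_concentration_table <- function(table) {
  needed <- c("group", "subject", "time_point", "metabolite", "concentration", "crlb")
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_invalid("concentration table must be a non-empty data frame")
  }
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop_invalid("concentration table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(table$concentration <= 0)) {
    stop_invalid("all concentrations must be strictly positive")
  }
  if (any(table$crlb < 0)) stop_invalid("CRLB percentages must be >= 0")
  key <- paste(table$group, table$subject, table$time_point, table$metabolite)
  if (anyDuplicated(key)) {
    stop_invalid("duplicate (group, subject, time_point, metabolite) records")
  }
  invisible(table)
}
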