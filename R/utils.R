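# internal helpers shared across modules

# read a text file tolerating CRLF line endings
read_lines_clean <- function(path) {
  x <- readLines(path, warn = FALSE)
  sub("\r$", "", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# truncated-normal draws by rejection; lower bound only
rnorm_trunc <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}
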