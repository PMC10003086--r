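# Internal helpers shared across modules.

# Canonical genotype call alphabet used everywhere downstream of I/O.
CALL_CODES <- c("P1", "P2", "HET", "MISSING")

`%||%` <- function(a, b) if (is.null(a)) b else a

other_parent <- function(x) {
  out <- x
  out[x == "P1"] <- "P2"
  out[x == "P2"] <- "P1"
  out
}

is_informative <- function(x) x == "P1" | x == "P2"

stop_mm <- function(...) stop(..., call. = FALSE)

warn_mm <- function(...) warning(..., call. = FALSE)

# Merge possibly-overlapping closed bp intervals (sorted by start within chrom).
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}
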