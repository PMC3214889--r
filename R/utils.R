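`%||%` <- function(a, b) if (is.null(a)) b else a

# exact comparison of two non-negative integer-valued fractions a/b > c/d;
# counts stay far below 2^26 so the double products are exact
frac_gt <- function(a, b, c, d) {
  if (b == 0 && d == 0) return(FALSE)
  if (b == 0) return(1 > c / d)
  if (d == 0) return(a / b > 1)
  a * d > c * b
}

pd_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

pd_log <- function(fmt, ...) message(sprintf(fmt, ...))

pair_key <- function(a, b) paste(a, b, sep = "\r")
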