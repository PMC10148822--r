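# internal numeric helpers

# round() in R rounds half to even; extrapolated neuron totals use
# half-away-from-zero
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# standard error of the mean; sample SD (n-1), NA for n = 1
semOf <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

# SD with selectable convention: sample (n-1) or population (n)
sdOf <- function(x, type = c("sample", "population")) {
  type <- match.arg(type)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (type == "sample") {
    if (n < 2L) return(NA_real_)
    stats::sd(x)
  } else {
    sqrt(sum((x - mean(x))^2) / n)
  }
}
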