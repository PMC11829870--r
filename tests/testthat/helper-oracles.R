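# Independent sort-based oracle: quartiles by linear interpolation between
# order statistics, written out longhand (shares no code with the package).
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}
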