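# Independent brute-force re-statement of the trajectory rule, kept
# deliberately literal: enumerate the difference vector, check the "always"
# conditions, then the first-difference + ratio conditions.
oracle_trajectory <- function(ld) {
  d <- ld[-1] - ld[-length(ld)]
  always_pos <- TRUE
  always_neg <- TRUE
  sum_pos <- 0
  sum_neg <- 0
  for (x in d) {
    if (x <= 0) always_pos <- FALSE
    if (x >= 0) always_neg <- FALSE
    if (x > 0) sum_pos <- sum_pos + x
    if (x < 0) sum_neg <- sum_neg + abs(x)
  }
  up_ratio <- d[1] > 0 &&
    (if (sum_neg == 0) sum_pos > 0 else sum_pos / sum_neg > 2)
  down_ratio <- d[1] < 0 &&
    (if (sum_pos == 0) sum_neg > 0 else sum_neg / sum_pos > 2)
  if (always_pos || up_ratio) return("up")
  if (always_neg || down_ratio) return("down")
  "fluctuate"
}
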