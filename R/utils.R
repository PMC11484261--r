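## Internal helpers shared across modules.

## round() in R is banker's rounding; published proportion tables use
## conventional half-up rounding, so it is implemented explicitly.
roundHalfUp <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Strip IMGT allele suffixes: "TRBV20-1*01" -> "TRBV20-1".
stripAllele <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  sub("\\*.*$", "", x)
}

## Two-sided tail probability of the t distribution via the regularized
## incomplete beta function: P(|T| >= t) = I_{df/(df+t^2)}(df/2, 1/2).
tTail2 <- function(t, df) {
  stats::pbeta(df / (df + t^2), df / 2, 0.5)
}

## Upper tail of the chi-square distribution via the regularized upper
## incomplete gamma function: P(X >= x) = Q(df/2, x/2).
chisqTail <- function(x, df) {
  stats::pgamma(x / 2, shape = df / 2, lower.tail = FALSE)
}

## Upper tail of the F distribution via the regularized incomplete beta:
## P(F >= f) = I_{df2/(df2 + df1 f)}(df2/2, df1/2).
fTail <- function(f, df1, df2) {
  stats::pbeta(df2 / (df2 + df1 * f), df2 / 2, df1 / 2)
}

## stop() with a consistent prefix and no call echo.
bail <- function(...) stop(..., call. = FALSE)

## match.arg with a clearer error for unknown labels coming from user config.
matchChoice <- function(value, choices, what) {
  if (length(value) != 1L || !value %in% choices)
    bail("unknown ", what, " '", paste(value, collapse = ","),
         "'; must be one of: ", paste(choices, collapse = ", "))
  value
}

## Deterministic per-sample seed derived from a master seed; kept within
## 32-bit integer range.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + 7919 * index) %% 2147483647)
}
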