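# Independent oracles used by the statistical tests. These deliberately do
# not share code paths with the package implementation.

# Hypergeometric upper tail by direct pmf enumeration: the pmf vector over
# the whole support is built from lchoose at the lower end plus the
# multiplicative recurrence, then suffix-summed. Returns the full tail
# vector P(X >= i) for i over the support.
hyper_tail_enum <- function(K, n, N) {
  i_min <- max(0, K + n - N)
  i_max <- min(K, n)
  pm <- numeric(i_max - i_min + 1)
  pm[1] <- exp(lchoose(K, i_min) + lchoose(N - K, n - i_min) - lchoose(N, n))
  if (i_max > i_min) {
    for (i in i_min:(i_max - 1)) {
      pm[i - i_min + 2] <- pm[i - i_min + 1] *
        (K - i) * (n - i) / ((i + 1) * (N - K - n + i + 1))
    }
  }
  rev(cumsum(rev(pm)))
}

hyper_tail_oracle <- function(k, K, n, N) {
  i_min <- max(0, K + n - N)
  i_max <- min(K, n)
  if (k <= i_min) return(1)
  tail <- hyper_tail_enum(K, n, N)
  tail[k - i_min + 1]
}

# Exact big-integer hypergeometric tails via Python's fractions.Fraction;
# takes a data.frame of (k, K, n, N) and returns exact tail probabilities
# rounded only at the final float conversion.
hyper_tail_python_exact <- function(cases) {
  script <- tempfile(fileext = ".py")
  infile <- tempfile(fileext = ".tsv")
  write.table(cases[, c("k", "K", "n", "N")], infile, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  writeLines(c(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "for line in open(sys.argv[1]):",
    "    k, K, n, N = map(int, line.split())",
    "    tot = comb(N, n)",
    "    tail = sum(Fraction(comb(K, i) * comb(N - K, n - i), tot)",
    "               for i in range(k, min(K, n) + 1))",
    "    print(repr(float(tail)))"
  ), script)
  out <- suppressWarnings(system2("python", c(script, infile), stdout = TRUE))
  as.numeric(out)
}

# Literal O(m^2) Benjamini-Hochberg step-up: for each p_i, the minimum of
# p_j * m / rank(p_j) over all p_j >= p_i, ranks counted with ties at
# their largest position.
bh_brute <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    js <- which(p >= pi)
    min(1, min(vapply(js, function(j) p[j] * m / sum(p <= p[j]), 1.0)))
  }, 1.0)
}
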