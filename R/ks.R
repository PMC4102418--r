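# One-sided one-sample Kolmogorov-Smirnov machinery.
#
# The enrichment direction of interest is "sample stochastically smaller
# than Uniform(0,1)", i.e. the empirical CDF lies above the diagonal, with
# statistic D+ = max_i (i/n - u_(i)).
#
# P(D+ >= d) is computed exactly for n <= 140 by the Birnbaum-Tingey
# formula
#   p = d * sum_{j=0}^{floor(n(1-d))} C(n,j) (d + j/n)^(j-1) (1 - d - j/n)^(n-j)
# and by the conservative asymptotic tail exp(-2 n d^2) for larger n
# (by the sharp Dvoretzky-Kiefer-Wolfowitz bound the asymptotic form is an
# upper bound on the exact tail, so large-n p-values are never
# anti-conservative). The same formulas are mirrored in the compiled
# permutation engine (src/ssea_perm.cpp).

ks_stat_plus <- function(u) {
  n <- length(u)
  max((seq_len(n) / n) - sort(u))
}

ks_p_upper <- function(d, n) {
  if (is.na(d) || n < 1L) return(NA_real_)
  if (d <= 0) return(1)
  if (d >= 1) return(0)
  if (n > 140L) return(min(1, exp(-2 * n * d^2)))
  tmax <- floor(n * (1 - d) + 1e-12)
  j <- 0:tmax
  q <- d + j / n
  ok <- q < 1
  term <- numeric(length(j))
  term[ok] <- exp(lchoose(n, j[ok]) + (j[ok] - 1) * log(q[ok]) +
                    (n - j[ok]) * log1p(-q[ok]))
  term[!ok & (n - j) == 0L] <- 1
  min(1, max(0, d * sum(term)))
}
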