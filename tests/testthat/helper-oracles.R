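# independent brute-force oracles, coded from first principles
# (definitional sums of squares, explicit loops; deliberately unlike the
# vectorised implementation they check)

oracle_one_sample_t <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- sum((x - m)^2) / (n - 1)
  list(t = m / sqrt(s2 / n), df = n - 1,
       p = 2 * stats::pt(-abs(m / sqrt(s2 / n)), n - 1))
}

oracle_paired_t <- function(a, b) oracle_one_sample_t(a - b)

# y: n x a x b array, one observation per subject x cell
oracle_rm_anova <- function(y) {
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  g <- mean(y)
  m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean); m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- n * b * sum((m_a - g)^2)
  ss_b <- n * a * sum((m_b - g)^2)
  ss_ab <- 0
  for (i in seq_len(a)) for (j in seq_len(b)) {
    ss_ab <- ss_ab + n * (m_ab[i, j] - m_a[i] - m_b[j] + g)^2
  }
  ss_as <- 0
  for (s in seq_len(n)) for (i in seq_len(a)) {
    ss_as <- ss_as + b * (m_sa[s, i] - m_a[i] - m_s[s] + g)^2
  }
  ss_bs <- 0
  for (s in seq_len(n)) for (j in seq_len(b)) {
    ss_bs <- ss_bs + a * (m_sb[s, j] - m_b[j] - m_s[s] + g)^2
  }
  ss_abs <- 0
  for (s in seq_len(n)) for (i in seq_len(a)) for (j in seq_len(b)) {
    ss_abs <- ss_abs + (y[s, i, j] - m_sa[s, i] - m_sb[s, j] - m_ab[i, j] +
                          m_s[s] + m_a[i] + m_b[j] - g)^2
  }
  list(
    f_a = (ss_a / (a - 1)) / (ss_as / ((a - 1) * (n - 1))),
    f_b = (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (n - 1))),
    f_ab = (ss_ab / ((a - 1) * (b - 1))) /
      (ss_abs / ((a - 1) * (b - 1) * (n - 1)))
  )
}

# step-up BH by direct enumeration of the k thresholds
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  kmax <- 0
  for (k in seq_len(m)) {
    if (p[ord][k] <= k * q / m) kmax <- k
  }
  if (kmax == 0) {
    list(reject = rep(FALSE, m), critical_p = 0)
  } else {
    list(reject = p <= p[ord][kmax], critical_p = p[ord][kmax])
  }
}
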