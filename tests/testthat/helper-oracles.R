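# Independent oracles used across tests.

# Analytic squared-magnitude response of an order-n Butterworth low-pass
# applied twice (forward-backward): |H(f)|^2 = (1 + (f/fc)^(2n))^(-1).
butter_dual_gain <- function(f, fc, order) {
  1 / (1 + (f / fc)^(2 * order))
}

# Brute-force sums-of-squares decomposition of a complete within-subject
# 2x2 design (one observation per subject x cell), explicit loops only.
oracle_rm_2x2 <- function(df) {
  subjects <- sort(unique(df$participant))
  a_lv <- sort(unique(df$a))
  b_lv <- sort(unique(df$b))
  y <- function(s, ai, bi) {
    df$value[df$participant == s & df$a == ai & df$b == bi]
  }
  grand <- mean(df$value)
  m_s <- sapply(subjects, function(s) mean(df$value[df$participant == s]))
  m_a <- sapply(a_lv, function(ai) mean(df$value[df$a == ai]))
  m_b <- sapply(b_lv, function(bi) mean(df$value[df$b == bi]))
  names(m_s) <- subjects; names(m_a) <- a_lv; names(m_b) <- b_lv
  m_as <- outer(a_lv, subjects, Vectorize(function(ai, s)
    mean(df$value[df$a == ai & df$participant == s])))
  m_bs <- outer(b_lv, subjects, Vectorize(function(bi, s)
    mean(df$value[df$b == bi & df$participant == s])))
  m_ab <- outer(a_lv, b_lv, Vectorize(function(ai, bi)
    mean(df$value[df$a == ai & df$b == bi])))
  dimnames(m_as) <- list(a_lv, subjects)
  dimnames(m_bs) <- list(b_lv, subjects)
  dimnames(m_ab) <- list(a_lv, b_lv)
  n <- length(subjects); na <- length(a_lv); nb <- length(b_lv)

  ss_a <- n * nb * sum((m_a - grand)^2)
  ss_b <- n * na * sum((m_b - grand)^2)
  ss_as <- 0; ss_bs <- 0; ss_ab <- 0; ss_abs <- 0
  for (ai in a_lv) for (s in subjects) {
    ss_as <- ss_as + nb * (m_as[ai, s] - m_a[ai] - m_s[s] + grand)^2
  }
  for (bi in b_lv) for (s in subjects) {
    ss_bs <- ss_bs + na * (m_bs[bi, s] - m_b[bi] - m_s[s] + grand)^2
  }
  for (ai in a_lv) for (bi in b_lv) {
    ss_ab <- ss_ab + n * (m_ab[ai, bi] - m_a[ai] - m_b[bi] + grand)^2
  }
  for (ai in a_lv) for (bi in b_lv) for (s in subjects) {
    ss_abs <- ss_abs +
      (y(s, ai, bi) - m_ab[ai, bi] - m_as[ai, s] - m_bs[bi, s] +
         m_a[ai] + m_b[bi] + m_s[s] - grand)^2
  }
  ss_a <- unname(ss_a); ss_b <- unname(ss_b); ss_ab <- unname(ss_ab)
  ss_as <- unname(ss_as); ss_bs <- unname(ss_bs); ss_abs <- unname(ss_abs)
  f_stat <- function(ss_e, df_e, ss_r, df_r) (ss_e / df_e) / (ss_r / df_r)
  list(
    a = list(F = f_stat(ss_a, na - 1, ss_as, (na - 1) * (n - 1)),
             peta = ss_a / (ss_a + ss_as),
             df = c(na - 1, (na - 1) * (n - 1))),
    b = list(F = f_stat(ss_b, nb - 1, ss_bs, (nb - 1) * (n - 1)),
             peta = ss_b / (ss_b + ss_bs),
             df = c(nb - 1, (nb - 1) * (n - 1))),
    ab = list(F = f_stat(ss_ab, (na - 1) * (nb - 1), ss_abs,
                         (na - 1) * (nb - 1) * (n - 1)),
              peta = ss_ab / (ss_ab + ss_abs),
              df = c((na - 1) * (nb - 1), (na - 1) * (nb - 1) * (n - 1)))
  )
}

# One-way within-subject decomposition, explicit loops.
oracle_rm_oneway <- function(df) {
  subjects <- sort(unique(df$participant))
  a_lv <- sort(unique(df$a))
  grand <- mean(df$value)
  m_s <- sapply(subjects, function(s) mean(df$value[df$participant == s]))
  m_a <- sapply(a_lv, function(ai) mean(df$value[df$a == ai]))
  names(m_s) <- subjects; names(m_a) <- a_lv
  n <- length(subjects); na <- length(a_lv)
  ss_a <- n * sum((m_a - grand)^2)
  ss_err <- 0
  for (ai in a_lv) for (s in subjects) {
    yy <- df$value[df$a == ai & df$participant == s]
    ss_err <- ss_err + (yy - m_a[ai] - m_s[s] + grand)^2
  }
  ss_a <- unname(ss_a); ss_err <- unname(ss_err)
  list(F = (ss_a / (na - 1)) / (ss_err / ((na - 1) * (n - 1))),
       peta = ss_a / (ss_a + ss_err),
       df = c(na - 1, (na - 1) * (n - 1)))
}

# Direct-formula paired t (independent of stats::t.test).
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1),
       dz = mean(d) / sd(d))
}
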