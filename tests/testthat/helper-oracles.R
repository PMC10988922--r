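# Independent textbook-formula oracles. These deliberately avoid stats::cor
# and stats::t.test so they can cross-check the package's computation paths.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# mid-ranks (average ranks for ties) computed by explicit enumeration
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    less + (eq + 1) / 2
  }, numeric(1))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

oracle_var <- function(x) sum((x - mean(x))^2) / (length(x) - 1)

oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * oracle_var(a) + (nb - 1) * oracle_var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

oracle_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- oracle_var(a) / na
  vb <- oracle_var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}
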