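# Independent brute-force oracles: plain-formula evaluations kept
# separate from the implementation paths they check.

welch_oracle <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

chisq_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  x2 <- sum((m - e)^2 / e)
  list(x2 = x2, p = pchisq(x2, df = 1, lower.tail = FALSE))
}

accuracy_oracle <- function(ba, ca) {
  mx <- mean(ba); my <- mean(ca)
  list(mae = mean(abs(ba - ca)),
       rmse = sqrt(mean((ba - ca)^2)),
       r = sum((ba - mx) * (ca - my)) /
         sqrt(sum((ba - mx)^2) * sum((ca - my)^2)),
       r2 = 1 - sum((ca - ba)^2) / sum((ca - my)^2))
}
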