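# Independent brute-force oracles, coded from the textbook definitions.
oracle_anova <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - gm)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  k <- length(groups)
  N <- length(all)
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

oracle_tamhane <- function(groups) {
  k <- length(groups)
  m <- choose(k, 2)
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    xi <- groups[[i]]; xj <- groups[[j]]
    vi <- var(xi) / length(xi)
    vj <- var(xj) / length(xj)
    t <- (mean(xi) - mean(xj)) / sqrt(vi + vj)
    df <- (vi + vj)^2 / (vi^2 / (length(xi) - 1) + vj^2 / (length(xj) - 1))
    p <- 2 * pt(abs(t), df, lower.tail = FALSE)
    out <- rbind(out, data.frame(i = i, j = j, t = t, df = df, p = p,
                                 adj = min(1, 1 - (1 - p)^m)))
  }
  out
}
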