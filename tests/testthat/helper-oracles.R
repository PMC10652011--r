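## Independent oracle implementations used across tests. These are written
## directly from the textbook formulas and never call the package functions
## they check.

welchOracle <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  va <- sum((a - ma)^2) / (length(a) - 1)
  vb <- sum((b - mb)^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

chao1Oracle <- function(x) {
  x <- x[x > 0]
  sum(x > 0) + sum(x == 1) * (sum(x == 1) - 1) / (2 * (sum(x == 2) + 1))
}

shannonNormOracle <- function(x) {
  x <- x[x > 0]
  if (length(x) == 1) return(0)
  p <- x / sum(x)
  -sum(p * log(p)) / log(length(x))
}

heipOracle <- function(x) {
  x <- x[x > 0]
  if (length(x) == 1) return(1)
  p <- x / sum(x)
  (exp(-sum(p * log(p))) - 1) / (length(x) - 1)
}

## product-limit by direct enumeration
kmOracle <- function(time, event) {
  s <- 1
  out <- NULL
  for (t in sort(unique(time[event]))) {
    n <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

## adjusted Rand index (contingency-table formula)
ariOracle <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- ai * bj / n2
  (sumij - exp_) / ((ai + bj) / 2 - exp_)
}

randomCdr3s <- function(n, seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(sample(10:16, n, replace = TRUE), function(l)
    paste0("C", paste(sample(aa, l - 2, replace = TRUE), collapse = ""),
           "F"), character(1))
}
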