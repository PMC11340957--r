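# Shared fixtures, built in code at test time.

# A minimal PhaseImageSet where every phase equals `value` everywhere.
uniformImageSet <- function(value = 100, dim = c(10, 10), spacing = c(1, 1)) {
  imgs <- stats::setNames(
    replicate(6, matrix(value, dim[1], dim[2]), simplify = FALSE),
    c("ip", "oop", "nc", "art", "pv", "del"))
  new("PhaseImageSet", images = imgs, spacing = spacing)
}

maskWithAllLabels <- function(dim = c(10, 10)) {
  m <- matrix(0L, dim[1], dim[2])
  m[1, 1:3] <- 1L; m[2, 1:3] <- 2L; m[3, 1:3] <- 3L
  new("MaskSet", labels = m, labelMap = c(psm_left = 1L, psm_right = 2L,
                                          aorta = 3L))
}

# Exhaustive Mann-Whitney U (count of (a, b) pairs with a > b, ties 1/2).
bruteU <- function(a, b) {
  g <- expand.grid(a = a, b = b)
  sum(g$a > g$b) + 0.5 * sum(g$a == g$b)
}

# Exact two-sided permutation p-value for the Mann-Whitney U statistic.
exactMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2, function(i) bruteU(pooled[i], pooled[-i]))
  obs <- bruteU(a, b)
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (fixed margins) no more likely than
# the observed one.
exactFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- stats::dhyper(ks, r1, n - r1, c1)
  obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}
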