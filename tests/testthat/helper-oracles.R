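# Independent oracles used to validate the score-interval machinery.
# The restricted MLEs are found by numerical likelihood maximization
# (stats::optimize), not by the closed forms the package uses, and the
# interval endpoints come from a two-stage grid over the difference rather
# than from root-finding.

# log-likelihood of two independent binomials under p1 - p2 = d
indep_loglik <- function(p2, d, x1, n1, x2, n2) {
  p1 <- p2 + d
  lx <- function(x, n, p) {
    if (p <= 0) return(if (x == 0) 0 else -Inf)
    if (p >= 1) return(if (x == n) 0 else -Inf)
    x * log(p) + (n - x) * log(1 - p)
  }
  lx(x1, n1, p1) + lx(x2, n2, p2)
}

oracle_score_stat_independent <- function(x1, n1, x2, n2, d, inflate = TRUE) {
  lo <- max(0, -d)
  hi <- min(1, 1 - d)
  if (hi - lo < 1e-12) return(Inf)
  opt <- stats::optimize(indep_loglik, c(lo, hi), d = d, x1 = x1, n1 = n1,
                         x2 = x2, n2 = n2, maximum = TRUE, tol = 1e-12)
  p2t <- opt$maximum
  p1t <- p2t + d
  v <- p1t * (1 - p1t) / n1 + p2t * (1 - p2t) / n2
  if (inflate) v <- v * (n1 + n2) / (n1 + n2 - 1)
  num <- x1 / n1 - x2 / n2 - d
  if (v <= 0) return(if (num == 0) 0 else sign(num) * Inf)
  num / sqrt(v)
}

# paired multinomial log-likelihood profiled over the discordant cell q21
# under p12 - p21 = d (b pairs favor test 1, c pairs favor test 2)
paired_loglik <- function(q21, d, b, c, n) {
  p12 <- q21 + d
  pcon <- 1 - 2 * q21 - d
  lx <- function(x, p) {
    if (p <= 0) return(if (x == 0) 0 else -Inf)
    x * log(p)
  }
  lx(b, p12) + lx(c, q21) + lx(n - b - c, pcon)
}

oracle_tango_stat <- function(b, c, n, d) {
  lo <- max(0, -d)
  hi <- (1 - d) / 2
  if (hi - lo < 1e-12) {
    q21 <- lo
  } else {
    opt <- stats::optimize(paired_loglik, c(lo, hi), d = d, b = b, c = c,
                           n = n, maximum = TRUE, tol = 1e-12)
    q21 <- opt$maximum
  }
  v <- n * (2 * q21 + d * (1 - d))
  num <- b - c - n * d
  if (v <= 0) return(if (num == 0) 0 else sign(num) * Inf)
  num / sqrt(v)
}

# endpoints of {d : |zfun(d)| <= zcrit} by a coarse-then-fine grid search;
# `fine` is the resolution of the returned endpoints
oracle_grid_invert <- function(zfun, level = 0.95, coarse = 1e-3,
                               fine = 1e-6) {
  zcrit <- qnorm(1 - (1 - level) / 2)
  grid <- seq(-1, 1, by = coarse)
  inside <- vapply(grid, function(d) abs(zfun(d)) <= zcrit, logical(1))
  if (!any(inside)) stop("oracle: empty acceptance region")
  lo_c <- grid[which(inside)[1]]
  hi_c <- grid[rev(which(inside))[1]]
  refine <- function(from, to) {
    g <- seq(max(-1, from), min(1, to), by = fine)
    ok <- vapply(g, function(d) abs(zfun(d)) <= zcrit, logical(1))
    g[ok]
  }
  lo_fine <- refine(lo_c - coarse, lo_c + coarse)
  hi_fine <- refine(hi_c - coarse, hi_c + coarse)
  c(min(lo_fine), max(hi_fine))
}
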