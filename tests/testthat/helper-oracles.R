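# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Cosinor least squares by coarse grid over the acrophase followed by 1-d
# refinement; for each candidate phase the conditional fit in (M, A) is a
# plain linear regression on {1, cos(pi*t/12 - phi)}.
oracle_cosinor <- function(times, values) {
  rss_at <- function(phi) {
    x <- cos(pi * times / 12 - phi)
    f <- stats::lm(values ~ x)
    sum(stats::residuals(f)^2)
  }
  grid <- seq(0, 2 * pi, length.out = 145)[-145]
  r <- vapply(grid, rss_at, numeric(1))
  best <- grid[which.min(r)]
  opt <- stats::optimize(rss_at, interval = c(best - 0.1, best + 0.1),
                         tol = 1e-12)
  phi <- opt$minimum
  x <- cos(pi * times / 12 - phi)
  f <- stats::lm(values ~ x)
  a <- unname(stats::coef(f)[2])
  if (a < 0) { a <- -a; phi <- phi + pi }
  phi <- phi %% (2 * pi)
  list(mesor = unname(stats::coef(f)[1]), amplitude = a, acrophase = phi,
       beta = a * cos(phi), gamma = a * sin(phi))
}

# geNorm M by explicit double loop over gene pairs.
oracle_genorm_m <- function(qmat) {
  lq <- log2(qmat)
  g <- ncol(qmat)
  m <- numeric(g)
  for (j in seq_len(g)) {
    v <- c()
    for (k in seq_len(g)) {
      if (k == j) next
      v <- c(v, stats::sd(lq[, j] - lq[, k]))
    }
    m[j] <- mean(v)
  }
  names(m) <- colnames(qmat)
  m
}

# Duncan decisions for exactly 3 groups, evaluated directly: every pairwise
# range test with its span-specific critical value, plus the containment
# rule (if the extreme pair is homogeneous, all pairs are).
oracle_duncan3 <- function(groups, alpha = 0.05) {
  stopifnot(length(groups) == 3L)
  y <- unlist(groups); g <- factor(rep(1:3, lengths(groups)))
  tab <- stats::anova(stats::aov(y ~ g))
  mse <- tab$`Mean Sq`[2]; dfe <- tab$Df[2]
  n_h <- 3 / sum(1 / lengths(groups))
  means <- vapply(groups, mean, numeric(1))
  ord <- order(means, decreasing = TRUE)
  rp <- function(p) stats::qtukey((1 - alpha)^(p - 1), p, dfe) * sqrt(mse / n_h)
  m <- means[ord]
  sig13 <- (m[1] - m[3]) > rp(3)
  sig12 <- sig13 && (m[1] - m[2]) > rp(2)
  sig23 <- sig13 && (m[2] - m[3]) > rp(2)
  # return significance matrix in original group order
  out <- matrix(FALSE, 3, 3)
  out[ord[1], ord[3]] <- out[ord[3], ord[1]] <- sig13
  out[ord[1], ord[2]] <- out[ord[2], ord[1]] <- sig12
  out[ord[2], ord[3]] <- out[ord[3], ord[2]] <- sig23
  out
}

# shared-letter predicate from a duncan_letters() result
shares_letter <- function(letters_vec, i, j) {
  a <- strsplit(letters_vec[i], "")[[1]]
  b <- strsplit(letters_vec[j], "")[[1]]
  length(intersect(a, b)) > 0
}

# the nine-ZT, six-replicate sampling grid used across tests
design_zts <- function() seq(0, 24, by = 3)
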