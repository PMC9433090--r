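# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the code paths they check.

# hypergeometric tail probabilities for a 2x2 table by direct enumeration
# with choose(); table = rbind(c(a, b), c(c, d)), margins fixed
oracle_fisher_p <- function(tab, alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  switch(alternative,
    greater = sum(probs[xs >= a]),
    less = sum(probs[xs <= a]),
    two.sided = {
      # minimum-likelihood rule, matching the exact test's convention
      sum(probs[probs <= probs[xs == a] * (1 + 1e-7)])
    }
  )
}

# type-7 (linear interpolation) percentile computed from the definition
oracle_percentile <- function(x, q) {
  s <- sort(x)
  h <- (length(x) - 1) * q / 100
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (if (lo + 2 <= length(s)) s[lo + 2] - s[lo + 1] else 0)
}

# sort-and-middle median, avoiding stats::median
oracle_median <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_moving_median <- function(series, window) {
  n <- length(series)
  left <- floor((window - 1) / 2)
  right <- window - 1 - left
  sapply(seq_len(n), function(i) {
    oracle_median(series[max(1, i - left):min(n, i + right)])
  })
}

# exhaustive two-sided permutation p-value for a difference in means
oracle_permutation_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  obs <- abs(mean(a) - mean(b))
  diffs <- apply(idx, 2, function(i) {
    abs(mean(pooled[i]) - mean(pooled[-i]))
  })
  mean(diffs >= obs - 1e-12)
}

# balanced two-way ANOVA sums of squares from the textbook formulas
oracle_anova_ss <- function(y, a, b) {
  gm <- mean(y)
  ss <- function(groups) {
    means <- tapply(y, groups, mean)
    counts <- tapply(y, groups, length)
    sum(counts * (means - gm)^2)
  }
  ss_a <- ss(a); ss_b <- ss(b)
  cell_means <- tapply(y, list(a, b), mean)
  cell_n <- tapply(y, list(a, b), length)
  ss_cells <- sum(cell_n * (cell_means - gm)^2)
  list(a = ss_a, b = ss_b, ab = ss_cells - ss_a - ss_b,
       resid = sum((y - cell_means[cbind(a, b)])^2))
}

# dense point-sampling approximation of grid coverage (step much smaller
# than a grid square, so no cell is skipped)
oracle_coverage_sampled <- function(track, square_mm, plate_diameter,
                                    step = 0.01) {
  origin <- -plate_diameter / 2
  cells <- character(0)
  for (i in seq_len(nrow(track) - 1)) {
    len <- sqrt((track$x_mm[i + 1] - track$x_mm[i])^2 +
                  (track$y_mm[i + 1] - track$y_mm[i])^2)
    ts <- seq(0, 1, length.out = max(2, ceiling(len / step)))
    px <- track$x_mm[i] + ts * (track$x_mm[i + 1] - track$x_mm[i])
    py <- track$y_mm[i] + ts * (track$y_mm[i + 1] - track$y_mm[i])
    cells <- c(cells, paste(floor((px - origin) / square_mm),
                            floor((py - origin) / square_mm)))
  }
  length(unique(cells))
}

# shared fixture scale for atlas-based tests: the family and its upregulated
# subset at the size of a realistic chemoreceptor repertoire
atlas_fixture_genes <- function() {
  genes <- sprintf("chem%04d", 1:1365)
  list(genes = genes, up = genes[1:133])
}
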