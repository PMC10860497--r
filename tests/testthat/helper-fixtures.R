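# Shared fixtures: everything is generated in code at test time.

# small canvas keeps pixel-exhaustive assertions fast
tiny_spec <- function(n_features = 1, width = 48, height = 48,
                      texture_amplitude = 0, render_seed = 7L) {
  demo_scene_spec(n_features = n_features, width = width, height = height,
                  texture_amplitude = texture_amplitude,
                  render_seed = render_seed)
}

yellow <- c(233, 212, 80)
orange <- c(227, 134, 61)
test_pair <- list(Yellow = yellow, Orange = orange)

tiny_set <- function(n_features = 1, ...) {
  build_composite_set(tiny_spec(n_features, ...), 1L, test_pair)
}

# brute-force linear interpolation oracle, evaluated pixel by pixel
oracle_morph_frame <- function(start, end, i, n) {
  out <- start
  for (idx in seq_along(start)) {
    out[idx] <- floor(start[idx] + (i / (n - 1)) * (end[idx] - start[idx]) + 0.5)
  }
  out
}

# --- independent long-hand statistics oracles -----------------------------

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1,
       p_two = 2 * pt(-abs(t), n - 1), p_less = pt(t, n - 1))
}

oracle_two_prop_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  # normal tail via numerical integration, independent of pnorm
  tail <- integrate(dnorm, abs(z), Inf, rel.tol = 1e-14)$value
  list(z = z, p = 2 * tail)
}

oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  col_means <- colMeans(m); row_means <- rowMeans(m)
  ss_level <- n * sum((col_means - grand)^2)
  ss_subj <- k * sum((row_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_resid <- ss_tot - ss_level - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f <- (ss_level / df1) / (ss_resid / df2)
  list(f = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, p = 2 * pt(-abs(t), n - 2))
}

# write a coded-responses CSV and return its path
write_responses_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}
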