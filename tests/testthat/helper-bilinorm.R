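# Shared fixtures and independent oracles for the test suite.

# Convenience patient: age expressed in hours after a fixed birth time.
make_patient <- function(ga = 38, bw = 3200, tsb = 10, age_h = 48,
                         risk = "none_declared", unit = "mg_dl") {
  birth <- as.POSIXct("2019-03-01 00:00:00", tz = "UTC")
  patient_record(ga_weeks = ga, birth_datetime = birth,
                 record_datetime = birth + age_h * 3600, bw_g = bw,
                 tsb_value = tsb, tsb_unit = unit, risk_factors = risk)
}

make_record <- function(..., pt_given = FALSE, exchange_given = FALSE,
                        epoch = "pre") {
  treatment_record(make_patient(...), pt_given = pt_given,
                   exchange_given = exchange_given, epoch = epoch)
}

# Independent piecewise-linear evaluator: explicit segment search + clamp,
# no approx().
piecewise_eval <- function(xs, ys, q) {
  vapply(q, function(x) {
    if (x <= xs[1]) return(ys[1])
    n <- length(xs)
    if (x >= xs[n]) return(ys[n])
    i <- max(which(xs <= x))
    ys[i] + (ys[i + 1] - ys[i]) * (x - xs[i]) / (xs[i + 1] - xs[i])
  }, numeric(1))
}

# Independent Pearson chi-square: explicit O/E summation over cells plus the
# chi-square survival function.
chisq_oracle <- function(m) {
  m <- as.matrix(m)
  n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      stat <- stat + (m[i, j] - e)^2 / e
    }
  }
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Random non-degenerate r x 2 count table.
random_table <- function() {
  repeat {
    r <- sample(2:5, 1)
    m <- matrix(rpois(2 * r, lambda = sample(c(3, 20, 80), 1)), nrow = r)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# A structurally valid guideline expressed as a plain list, for constructing
# deliberate violations.
guideline_as_list <- function() {
  path <- system.file("extdata", "guideline_default.yaml", package = "bilinorm")
  yaml::read_yaml(path)
}
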