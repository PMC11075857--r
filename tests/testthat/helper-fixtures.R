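# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

basic_schema <- function(log_wbc = FALSE, znorm_age = FALSE) {
  feature_schema(list(
    list(name = "age", kind = "continuous", role = "covariate",
         znorm = znorm_age),
    list(name = "SBP", kind = "continuous", role = "covariate"),
    list(name = "DBP", kind = "continuous", role = "covariate"),
    list(name = "WBC", kind = "continuous", role = "covariate",
         log = log_wbc, shift = if (log_wbc) 1 else 0),
    list(name = "loc", kind = "categorical", role = "covariate",
         levels = c("lobar", "basal", "thalamus")),
    list(name = "T", kind = "binary", role = "treatment"),
    list(name = "Y", kind = "binary", role = "outcome")
  ))
}

basic_ds <- function(n = 8, seed = 42) {
  set.seed(seed)
  x <- data.frame(
    age = round(stats::rnorm(n, 60, 10), 1),
    SBP = round(stats::rnorm(n, 175, 15), 1),
    DBP = round(stats::rnorm(n, 95, 10), 1),
    WBC = round(stats::rexp(n, 1 / 7), 2),
    loc = sample(c("lobar", "basal", "thalamus"), n, replace = TRUE)
  )
  trial_dataset(x, rep_len(c(1, 0), n), rep_len(c(1, 0, 0, 1), n),
                basic_schema())
}

# Tiny two-covariate dataset where a binary feature fully determines a
# planted uplift difference.
planted_binary_ds <- function(n = 400, seed = 1, effect = 0.35) {
  set.seed(seed)
  g <- rbinom(n, 1, 0.5)          # the informative binary feature
  noise1 <- rnorm(n)
  noise2 <- sample(c("a", "b", "c"), n, replace = TRUE)
  tr <- rbinom(n, 1, 0.5)
  p <- 0.3 + effect * g * tr
  y <- rbinom(n, 1, p)
  schema <- feature_schema(list(
    list(name = "g", kind = "binary", role = "covariate"),
    list(name = "z", kind = "continuous", role = "covariate"),
    list(name = "c1", kind = "categorical", role = "covariate",
         levels = c("a", "b", "c")),
    list(name = "T", kind = "binary", role = "treatment"),
    list(name = "Y", kind = "binary", role = "outcome")
  ))
  trial_dataset(data.frame(g = g, z = noise1, c1 = noise2), tr, y, schema)
}

# Independent gain oracle: direct transcription of the split-gain formula
# (Jeffreys-smoothed rates, weighted child KL minus parent KL), written
# without reusing the package's node-statistics path.
oracle_kl <- function(p, q) p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))

oracle_gain <- function(t, y, right) {
  sm <- function(s, n) (s + 0.5) / (n + 1)
  cnt <- function(mask) {
    c(nt = sum(t[mask] == 1), nc = sum(t[mask] == 0),
      st = sum(y[mask][t[mask] == 1]), sc = sum(y[mask][t[mask] == 0]))
  }
  pa <- cnt(rep(TRUE, length(t))); le <- cnt(!right); ri <- cnt(right)
  if (le["nt"] == 0 || le["nc"] == 0 || ri["nt"] == 0 || ri["nc"] == 0)
    return(NA_real_)
  kl <- function(z) oracle_kl(sm(z["st"], z["nt"]), sm(z["sc"], z["nc"]))
  n <- length(t)
  unname(((le["nt"] + le["nc"]) / n) * kl(le) +
           ((ri["nt"] + ri["nc"]) / n) * kl(ri) - kl(pa))
}

# Exhaustive best-split oracle over the same candidate space, with the same
# tie rule (schema feature order, ascending threshold).
oracle_best_split <- function(ds, k = 10) {
  best <- NULL; best_gain <- 0
  for (nm in names(ds$x)) {
    f <- ds$schema$features[[nm]]
    cands <- candidate_splits(ds$x[[nm]], f$kind, k = k, feature = nm,
                              all_levels = f$levels)
    for (cond in cands) {
      right <- if (cond$op == "in") as.character(ds$x[[nm]]) %in% cond$value
               else ds$x[[nm]] >= cond$value
      if (!any(right) || all(right)) next
      g <- oracle_gain(ds$treatment, ds$outcome, right)
      if (!is.na(g) && g > best_gain + 1e-12) {
        best_gain <- g
        best <- list(feature = nm, op = cond$op, value = cond$value, gain = g)
      }
    }
  }
  best
}

# Brute-force Qini from the stated prefix formula, one subject at a time
# (tie-free scores assumed), independent of the package's block construction.
oracle_qini <- function(y, t, ord) {
  n <- length(y)
  frac <- 0; gain <- 0
  for (i in seq_len(n)) {
    pre <- ord[seq_len(i)]
    nt <- sum(t[pre] == 1); nc <- sum(t[pre] == 0)
    yt <- sum(y[pre][t[pre] == 1]); yc <- sum(y[pre][t[pre] == 0])
    g <- if (nc == 0) yt else yt - yc * nt / nc
    frac <- c(frac, i / n); gain <- c(gain, g / n)
  }
  total <- gain[length(gain)]
  base <- frac * total
  trapz <- function(xv, yv) sum(diff(xv) * (head(yv, -1) + tail(yv, -1)) / 2)
  trapz(frac, gain) - trapz(frac, base)
}
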