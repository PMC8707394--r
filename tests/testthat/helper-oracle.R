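# Independent oracles for the agreement statistics.

# Reference ICC(2,1)/(2,k) via pingouin (python). Input: list of numeric
# matrices; output: one row per matrix with estimates and its (rounded to two
# decimals) confidence bounds.
pingouin_icc <- function(mats) {
  long <- do.call(rbind, lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    data.frame(id = i, t = rep(seq_len(nrow(m)), ncol(m)),
               r = rep(seq_len(ncol(m)), each = nrow(m)), v = as.vector(m))
  }))
  inp <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
  script <- tempfile(fileext = ".py")
  write.csv(long, inp, row.names = FALSE)
  writeLines(c(
    "import sys, pandas as pd, pingouin as pg",
    "df = pd.read_csv(sys.argv[1])",
    "rows = []",
    "for i, g in df.groupby('id'):",
    "    res = pg.intraclass_corr(g, 't', 'r', 'v')",
    "    a1 = res[res.Type == 'ICC(A,1)'].iloc[0]",
    "    ak = res[res.Type == 'ICC(A,k)'].iloc[0]",
    "    rows.append(dict(id=i, icc2=a1['ICC'], lo2=a1['CI95'][0], hi2=a1['CI95'][1],",
    "                     icc2k=ak['ICC'], lo2k=ak['CI95'][0], hi2k=ak['CI95'][1]))",
    "pd.DataFrame(rows).sort_values('id').to_csv(sys.argv[2], index=False)"
  ), script)
  status <- system2("python", c(script, inp, out), stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(out)) {
    stop("pingouin oracle failed to run")
  }
  read.csv(out)
}

# Reference ICC through a different route to the mean squares: the two-way
# ANOVA table of lm(), then the published F-based interval applied directly.
anova_icc <- function(m, conf_level = 0.95) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(v = as.vector(m),
                  row = factor(rep(seq_len(n), k)),
                  col = factor(rep(seq_len(k), each = n)))
  tab <- stats::anova(stats::lm(v ~ row + col, data = d))
  msr <- tab["row", "Mean Sq"]; msc <- tab["col", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  fj <- msc / mse
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * fj + b)^2 / (a^2 * fj^2 / (k - 1) + b^2 / ((k - 1) * (n - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  sb <- function(r) r * k / (1 + (k - 1) * r)
  estk <- (msr - mse) / (msr + (msc - mse) / n)
  list(est2 = est, lo2 = lo, hi2 = hi,
       est2k = estk, lo2k = sb(lo), hi2k = sb(hi))
}

# random ICC test matrices with row structure so estimates span the range
random_icc_matrices <- function(n_mats, seed) {
  set.seed(seed)
  lapply(seq_len(n_mats), function(i) {
    n <- sample(5:50, 1); k <- sample(2:5, 1)
    rowfx <- rnorm(n, 0, runif(1, 0, 3))
    colfx <- rnorm(k, 0, runif(1, 0, 1))
    outer(rowfx, colfx, `+`) + matrix(rnorm(n * k), n, k)
  })
}
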