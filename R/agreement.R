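# Agreement between event sources: night-level pairing, two-way
# random-effects ICC with F-based 95% CIs, Bland-Altman bias and limits of
# agreement with CIs, and kernel density summaries of the differences.

#' Pair event sources night by night
#'
#' Inner join of two or more event sets on (subject, night); the chosen
#' endpoint is extracted and expressed in minutes relative to the night's
#' reference midnight (the midnight ending the night's calendar date), so a
#' to-bed at 23:30 is -30 min and one at 00:15 the next morning is +15 min.
#' Rows with any missing source are dropped (complete-case analysis).
#'
#' @param ... two or more [inbed_events()] data frames (named arguments name
#'   the columns), or a single named list of them.
#' @param endpoint `"to_bed"` or `"out_of_bed"`.
#' @return A data frame of class `paired_times`: columns `subject`, `night`,
#'   then one numeric column per source.
#' @export
pair_by_night <- function(..., endpoint = c("to_bed", "out_of_bed")) {
  endpoint <- match.arg(endpoint)
  sources <- list(...)
  if (length(sources) == 1L && !inherits(sources[[1L]], "inbed_events") &&
      is.list(sources[[1L]])) {
    sources <- sources[[1L]]
  }
  if (length(sources) < 2L) stop("need at least two event sources", call. = FALSE)
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    names(sources) <- vapply(seq_along(sources), function(i) {
      src <- unique(sources[[i]]$source)
      if (length(src) == 1L && nzchar(src)) src else paste0("source", i)
    }, "")
  }
  cols <- lapply(names(sources), function(nm) {
    e <- sources[[nm]]
    key <- paste(e$subject_id, e$night_id, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      stop(sprintf("duplicate (subject, night) in source '%s': %s",
                   nm, gsub("\r", " / ", dup)), call. = FALSE)
    }
    mins <- minutes_past_reference_midnight(e[[endpoint]], e$night_id)
    data.frame(key = key, subject = e$subject_id,
               night = as.character(e$night_id), value = mins,
               stringsAsFactors = FALSE)
  })
  keys <- Reduce(intersect, lapply(cols, `[[`, "key"))
  keys <- sort(keys)
  out <- data.frame(
    subject = cols[[1L]]$subject[match(keys, cols[[1L]]$key)],
    night = cols[[1L]]$night[match(keys, cols[[1L]]$key)],
    stringsAsFactors = FALSE)
  for (i in seq_along(cols)) {
    out[[names(sources)[i]]] <- cols[[i]]$value[match(keys, cols[[i]]$key)]
  }
  out <- out[stats::complete.cases(out), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, endpoint = endpoint,
            class = c("paired_times", "data.frame"))
}

# minutes relative to the midnight that ends the night's calendar date;
# evening times are negative, morning times positive
minutes_past_reference_midnight <- function(ts, night_id) {
  tz <- attr(as.POSIXlt(ts), "tzone")[1L]
  if (is.null(tz) || !nzchar(tz)) tz <- ""
  ref <- as.POSIXct(paste(as.Date(night_id) + 1L, "00:00:00"), tz = tz)
  as.numeric(difftime(ts, ref, units = "mins"))
}

paired_matrix <- function(data) {
  if (inherits(data, "paired_times")) {
    as.matrix(data[, setdiff(names(data), c("subject", "night")), drop = FALSE])
  } else {
    as.matrix(data)
  }
}

#' Two-way random-effects intraclass correlation (absolute agreement)
#'
#' ICC from the two-way ANOVA decomposition of an n x k table (rows = nights,
#' columns = raters/methods): ICC(2,1) for single measures,
#'
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#'
#' and ICC(2,k) for the average of the k columns. 95% confidence intervals
#' use the F-distribution interval with the Satterthwaite-style effective
#' denominator degrees of freedom; the average-measures interval is the
#' Spearman-Brown transform of the single-measures interval. The result is
#' interpreted on the CI lower bound via [interpret_icc()].
#'
#' @param data a `paired_times` data frame from [pair_by_night()], or a
#'   numeric matrix (rows = subjects/nights, columns = raters/methods).
#' @param form `"single"` (ICC(2,1)) or `"average"` (ICC(2,k)).
#' @param conf_level confidence level (default 0.95).
#' @param min_rows minimum number of complete rows required (default 5).
#' @return An object of class `icc_result`: `estimate`, `ci_low`, `ci_high`,
#'   `model`, `form`, `n_rows`, `n_cols`, `interpretation` and the mean
#'   squares.
#' @export
icc <- function(data, form = c("single", "average"), conf_level = 0.95,
                min_rows = 5L) {
  form <- match.arg(form)
  x <- paired_matrix(data)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (k < 2L) stop("need at least two columns (raters/methods)", call. = FALSE)
  if (n < min_rows) {
    stop(sprintf("need at least %d complete rows, got %d", min_rows, n), call. = FALSE)
  }
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  sst <- sum((x - grand)^2)
  if (sst == 0) {
    stop(structure(class = c("icc_undefined", "error", "condition"),
                   list(message = "ICC undefined: zero total variance",
                        call = sys.call(-1))))
  }
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  est1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  if (mse == 0) {
    # no within-row disagreement at all: the interval collapses
    low1 <- up1 <- est1
  } else {
    fj <- msc / mse
    a_ <- k * est1 / (n * (1 - est1))
    b_ <- 1 + k * est1 * (n - 1) / (n * (1 - est1))
    v <- (a_ * fj + b_)^2 /
      (a_^2 * fj^2 / (k - 1) + b_^2 / ((k - 1) * (n - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    low1 <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    up1 <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  }

  sb <- function(r) r * k / (1 + (k - 1) * r)
  if (form == "single") {
    est <- est1; low <- low1; up <- up1
  } else {
    est <- (msr - mse) / (msr + (msc - mse) / n)
    low <- sb(low1); up <- sb(up1)
  }
  structure(list(
    estimate = est, ci_low = low, ci_high = up, conf_level = conf_level,
    model = "two-way random effects, absolute agreement",
    form = form, n_rows = n, n_cols = k,
    interpretation = interpret_icc(max(-1, min(1, low))),
    ms = c(MSR = msr, MSC = msc, MSE = mse)
  ), class = "icc_result")
}

#' @export
print.icc_result <- function(x, digits = 3, ...) {
  cat(sprintf("ICC(2,%s) = %.*f, %g%% CI [%.*f, %.*f]  (%s)\n",
              if (x$form == "single") "1" else "k",
              digits, x$estimate, 100 * x$conf_level,
              digits, x$ci_low, digits, x$ci_high, x$model))
  cat(sprintf("  n = %d rows x %d cols; interpretation (CI lower bound): %s\n",
              x$n_rows, x$n_cols, x$interpretation))
  invisible(x)
}

#' Interpret an ICC by its 95% CI lower bound
#'
#' Bands: below 0.5 poor, 0.5 to below 0.75 moderate, 0.75 to below 0.9
#' good, 0.9 and above excellent. Applied to the CI lower bound, the
#' conservative reading recommended for reliability studies.
#'
#' @param ci_low lower confidence bound in \[-1, 1\].
#' @return `"poor"`, `"moderate"`, `"good"` or `"excellent"`.
#' @export
interpret_icc <- function(ci_low) {
  stopifnot(all(ci_low >= -1 - 1e-9 & ci_low <= 1 + 1e-9))
  cut(ci_low, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |> as.character()
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented `reference - test`, so a positive bias means the
#' test method's timestamps are earlier than the reference's
#' (underestimation). Bias is the mean difference; the limits of agreement
#' are `bias +/- loa_multiplier * SD` of the differences (1.96 by default; a
#' switch to exactly 2 is provided for the older convention). The bias CI
#' uses the t interval `bias +/- t * SD/sqrt(n)`; the LOA CIs use
#' `SE_LOA = sqrt(3 SD^2 / n)` with the same t quantile.
#'
#' @param test,ref equal-length numeric vectors of paired measurements
#'   (minutes), `n >= 3`.
#' @param loa_multiplier SD multiplier for the limits (default 1.96).
#' @param conf_level confidence level for all intervals (default 0.95).
#' @return An object of class `ba_result`: `bias`, `bias_ci`, `loa_lower`,
#'   `loa_lower_ci`, `loa_upper`, `loa_upper_ci`, `sd_diff`, `n`.
#' @export
bland_altman <- function(test, ref, loa_multiplier = 1.96, conf_level = 0.95) {
  if (length(test) != length(ref)) stop("test and ref lengths differ", call. = FALSE)
  ok <- stats::complete.cases(test, ref)
  d <- (ref - test)[ok]
  n <- length(d)
  if (n < 3L) stop("need at least 3 paired values", call. = FALSE)
  bias <- mean(d)
  sd_d <- stats::sd(d)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  se_bias <- sd_d / sqrt(n)
  se_loa <- sqrt(3 * sd_d^2 / n)
  loa_l <- bias - loa_multiplier * sd_d
  loa_u <- bias + loa_multiplier * sd_d
  structure(list(
    bias = bias, bias_ci = c(bias - tcrit * se_bias, bias + tcrit * se_bias),
    loa_lower = loa_l, loa_lower_ci = c(loa_l - tcrit * se_loa, loa_l + tcrit * se_loa),
    loa_upper = loa_u, loa_upper_ci = c(loa_u - tcrit * se_loa, loa_u + tcrit * se_loa),
    sd_diff = sd_d, n = n, loa_multiplier = loa_multiplier,
    conf_level = conf_level
  ), class = "ba_result")
}

#' @export
print.ba_result <- function(x, digits = 2, ...) {
  fmt <- function(v) sprintf("%.*f", digits, v)
  cat(sprintf("Bland-Altman (n = %d, differences = reference - test, minutes)\n", x$n))
  cat(sprintf("  bias      %s  [%s, %s]\n", fmt(x$bias),
              fmt(x$bias_ci[1]), fmt(x$bias_ci[2])))
  cat(sprintf("  lower LOA %s  [%s, %s]\n", fmt(x$loa_lower),
              fmt(x$loa_lower_ci[1]), fmt(x$loa_lower_ci[2])))
  cat(sprintf("  upper LOA %s  [%s, %s]\n", fmt(x$loa_upper),
              fmt(x$loa_upper_ci[1]), fmt(x$loa_upper_ci[2])))
  invisible(x)
}

#' Kernel density of paired differences
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth,
#' evaluated on a supplied or automatic grid; used for the
#' probability-density summaries of between-method differences. A
#' zero-variance input yields a degenerate spike representation instead.
#'
#' @param diffs numeric vector of differences, `n >= 2`.
#' @param grid evaluation points; default is 512 points spanning the data
#'   plus three bandwidths either side.
#' @param bw bandwidth override (default Silverman's `bw.nrd0`).
#' @return A list of class `diff_density`: `grid`, `density`, `bw`,
#'   `degenerate` (and `location` when degenerate).
#' @export
density_of_differences <- function(diffs, grid = NULL, bw = NULL) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2L) stop("need at least 2 differences", call. = FALSE)
  if (stats::sd(diffs) == 0) {
    if (is.null(grid)) grid <- diffs[1L] + seq(-1, 1, length.out = 3L)
    dens <- rep(0, length(grid))
    dens[which.min(abs(grid - diffs[1L]))] <- Inf
    return(structure(list(grid = grid, density = dens, bw = 0,
                          degenerate = TRUE, location = diffs[1L]),
                     class = "diff_density"))
  }
  if (is.null(bw)) bw <- stats::bw.nrd0(diffs)
  if (is.null(grid)) {
    grid <- seq(min(diffs) - 3 * bw, max(diffs) + 3 * bw, length.out = 512L)
  }
  dens <- vapply(grid, function(g) mean(stats::dnorm((g - diffs) / bw)) / bw,
                 numeric(1))
  structure(list(grid = grid, density = dens, bw = bw, degenerate = FALSE),
            class = "diff_density")
}

#' @export
print.diff_density <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<diff_density> degenerate spike at %g\n", x$location))
  } else {
    cat(sprintf("<diff_density> %d grid points, bw = %.3g\n", length(x$grid), x$bw))
  }
  invisible(x)
}

#' Plot the density of differences
#'
#' @param x a `diff_density`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.diff_density <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l",
                 xlab = "difference (min)", ylab = "density", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
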