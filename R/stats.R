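#' Simulate repeated measurement sessions
#'
#' Emulates examiners re-measuring the same objects: per object and session,
#' `measurement = true + session_bias + Normal(0, error_sd)`. Deterministic
#' given the seed. The output is a long-format measurement table compatible
#' with the reliability statistics.
#'
#' @param true_volumes numeric vector of true per-object values.
#' @param bias scalar or per-session vector of structural (systematic)
#'   session biases.
#' @param error_sd per-measurement random error sd (`>= 0`).
#' @param n_sessions number of sessions (default 2).
#' @param rng_seed integer seed.
#' @param unit unit label stored with the table (`"voxel"` or `"mm3"`).
#' @return A data.frame with columns `object_id`, `session_id`, `value` and
#'   attribute `unit`.
#' @export
simulate_measurement_sessions <- function(true_volumes, bias = 0, error_sd,
                                          n_sessions = 2L, rng_seed = 1L,
                                          unit = "mm3") {
  if (!is.numeric(true_volumes) || !length(true_volumes))
    nv_stop("`true_volumes` must be a non-empty numeric vector")
  if (error_sd < 0) nv_stop("`error_sd` must be >= 0")
  if (length(bias) == 1L) bias <- rep(bias, n_sessions)
  if (length(bias) != n_sessions) nv_stop("`bias` must be scalar or one value per session")
  m <- length(true_volumes)
  vals <- with_seed(rng_seed, {
    unlist(lapply(seq_len(n_sessions), function(s)
      true_volumes + bias[s] + stats::rnorm(m, 0, error_sd)))
  })
  out <- data.frame(object_id = rep(seq_len(m), times = n_sessions),
                    session_id = rep(seq_len(n_sessions), each = m),
                    value = vals)
  attr(out, "unit") <- unit
  out
}

#' Read / write a measurement table as CSV
#'
#' Columns `object_id`, `session_id`, `value`, `unit`.
#' @param path CSV path.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) nv_stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  need <- c("object_id", "session_id", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) nv_stop(sprintf("measurements CSV missing column(s): %s",
                                    paste(miss, collapse = ", ")))
  attr(df, "unit") <- if ("unit" %in% names(df)) as.character(df$unit[1]) else "mm3"
  df
}

#' @rdname read_measurements
#' @param table measurement data.frame.
#' @export
write_measurements <- function(table, path) {
  df <- table
  df$unit <- attr(table, "unit") %||% "mm3"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# extract paired session vectors from a long table
sessions_wide <- function(table, sessions = c(1, 2)) {
  x <- table$value[table$session_id == sessions[1]]
  y <- table$value[table$session_id == sessions[2]]
  ox <- table$object_id[table$session_id == sessions[1]]
  oy <- table$object_id[table$session_id == sessions[2]]
  if (length(x) != length(y) || !all(sort(ox) == sort(oy)))
    nv_stop("every object needs a value in both sessions")
  list(x = x[order(ox)], y = y[order(oy)])
}

#' Paired t-test on repeated measurements
#'
#' Classical paired t on the differences `d = x - y`: two-tailed p-value and
#' the 95% confidence interval of the mean difference, with `df = n - 1`.
#' Zero variance of the differences with a nonzero mean yields `t = +-Inf`,
#' `p = 0`, flagged by `degenerate = TRUE`.
#'
#' @param x,y paired measurement vectors (same objects, same order).
#' @return List with `t`, `df`, `p`, `mean_difference`, `ci95` (length 2).
#' @export
paired_t_test <- function(x, y) {
  check_paired(x, y)
  d <- x - y
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) return(list(t = 0, df = n - 1, p = 1, mean_difference = 0,
                             ci95 = c(0, 0), degenerate = FALSE))
    return(list(t = sign(md) * Inf, df = n - 1, p = 0, mean_difference = md,
                ci95 = c(md, md), degenerate = TRUE))
  }
  se <- sdd / sqrt(n)
  tt <- md / se
  q <- stats::qt(0.975, n - 1)
  list(t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1),
       mean_difference = md, ci95 = c(md - q * se, md + q * se),
       degenerate = FALSE)
}

#' Random error of duplicated measurements
#'
#' The per-measurement random error implied by two sessions: the sample
#' standard deviation (n-1 denominator) of the paired differences divided by
#' `sqrt(2)`.
#'
#' @param x,y paired measurement vectors.
#' @return Random error in the measurement units.
#' @export
random_error <- function(x, y) {
  check_paired(x, y)
  stats::sd(x - y) / sqrt(2)
}

#' Intraclass correlation coefficient for two sessions
#'
#' Single-measure ICC from the mean-squares decomposition of the n x 2
#' table. `model = "two_way_absolute_agreement"` (the default) is ICC(A,1)
#' of the two-way random model with absolute agreement - session biases
#' count as disagreement; `"one_way_random"` is ICC(1).
#'
#' @param x,y paired measurement vectors.
#' @param model `"two_way_absolute_agreement"` or `"one_way_random"`.
#' @return The ICC (dimensionless, `<= 1`).
#' @export
icc <- function(x, y, model = c("two_way_absolute_agreement", "one_way_random")) {
  model <- match.arg(model)
  check_paired(x, y)
  n <- length(x)
  k <- 2
  tab <- cbind(x, y)
  grand <- mean(tab)
  row_m <- rowMeans(tab)
  col_m <- colMeans(tab)
  if (all(tab == grand)) nv_stop("zero total variance: ICC undefined",
                                 class = "nasovol_computation_error")
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ms_rows <- ss_rows / (n - 1)
  if (model == "one_way_random") {
    ss_within <- ss_tot - ss_rows
    ms_within <- ss_within / (n * (k - 1))
    (ms_rows - ms_within) / (ms_rows + (k - 1) * ms_within)
  } else {
    ms_cols <- ss_cols / (k - 1)
    ss_err <- ss_tot - ss_rows - ss_cols
    ms_err <- ss_err / ((n - 1) * (k - 1))
    (ms_rows - ms_err) /
      (ms_rows + (k - 1) * ms_err + k * (ms_cols - ms_err) / n)
  }
}

#' Accuracy as a percentage of the gold standard
#'
#' @param measured_mm3 measured volume.
#' @param gs_mm3 gold-standard volume (> 0).
#' @param digits decimals in the reported percentage (default 1, the
#'   reporting convention for these accuracy tables).
#' @return `100 * measured / gs`, rounded to `digits`.
#' @export
percent_of_gs <- function(measured_mm3, gs_mm3, digits = 1) {
  if (any(gs_mm3 <= 0)) nv_stop("gold standard must be positive")
  round(100 * measured_mm3 / gs_mm3, digits)
}

#' Convert between voxel counts and cubic mm
#'
#' At 0.4 mm isotropic voxels one cubic mm is 15.625 voxels. Exact
#' arithmetic; the two directions are inverses.
#'
#' @param value numeric value(s) to convert.
#' @param direction `"counts_to_mm3"` or `"mm3_to_counts"`.
#' @param spacing voxel spacing, scalar (isotropic) or length 3 (mm).
#' @export
voxel_mm3_convert <- function(value, direction = c("counts_to_mm3", "mm3_to_counts"),
                              spacing = 0.4) {
  direction <- match.arg(direction)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) nv_stop("`spacing` must be positive")
  # one axis at a time: keeps the canonical decimal constants exact in
  # floating point (1 mm^3 at 0.4 mm voxels is exactly 15.625 counts)
  for (s in spacing)
    value <- if (direction == "counts_to_mm3") value * s else value / s
  value
}

#' Reliability report for two measurement sessions
#'
#' Bundles the reliability statistics the way an agreement table reports
#' them: ICC, random error, mean difference with its 95% CI, and the paired
#' t-test.
#'
#' @param x,y paired measurement vectors.
#' @param icc_model passed to [icc()].
#' @return List of class `nv_reliability`: `icc`, `random_error`,
#'   `mean_difference`, `ci95_low`, `ci95_high`, `t_statistic`, `df`, `p_value`.
#' @export
reliability_report <- function(x, y, icc_model = "two_way_absolute_agreement") {
  tt <- paired_t_test(x, y)
  structure(list(icc = icc(x, y, icc_model),
                 random_error = random_error(x, y),
                 mean_difference = tt$mean_difference,
                 ci95_low = tt$ci95[1], ci95_high = tt$ci95[2],
                 t_statistic = tt$t, df = tt$df, p_value = tt$p),
            class = "nv_reliability")
}

#' @export
print.nv_reliability <- function(x, ...) {
  cat("Reliability of paired measurement sessions\n")
  cat(sprintf("  ICC                : %.3f\n", x$icc))
  cat(sprintf("  Random error       : %.1f\n", x$random_error))
  cat(sprintf("  Mean difference    : %.1f  [%.1f, %.1f]\n",
              x$mean_difference, x$ci95_low, x$ci95_high))
  cat(sprintf("  Paired t (df = %d) : %.3f, p = %.3f\n", x$df, x$t_statistic, x$p_value))
  invisible(x)
}

#' Accuracy report against gold-standard volumes
#'
#' @param measured_mm3 named or unnamed numeric vector of measured volumes.
#' @param gs_mm3 matching gold-standard volumes.
#' @return data.frame with `object`, `measured_mm3`, `gs_mm3`, `percent_of_gs`.
#' @export
accuracy_report <- function(measured_mm3, gs_mm3) {
  if (length(measured_mm3) != length(gs_mm3))
    nv_stop("measured and gold-standard vectors must have equal length")
  nm <- names(measured_mm3) %||% paste0("object_", seq_along(measured_mm3))
  data.frame(object = nm,
             measured_mm3 = as.numeric(measured_mm3),
             gs_mm3 = as.numeric(gs_mm3),
             percent_of_gs = percent_of_gs(as.numeric(measured_mm3), as.numeric(gs_mm3)))
}

check_paired <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) nv_stop("measurements must be numeric")
  if (length(x) != length(y)) nv_stop("paired vectors must have equal length")
  if (length(x) < 2L) nv_stop("need at least 2 paired measurements")
  if (anyNA(x) || anyNA(y)) nv_stop("measurements must not contain NA")
  invisible(TRUE)
}
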