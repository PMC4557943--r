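# Statistics applied to event tables and group summaries. Conventions pinned
# down here: Pearson chi-square is always uncorrected (no Yates continuity
# correction); the Mann-Whitney U reported is min(U1, U2) with ties counted
# 0.5; median confidence intervals are percentile bootstrap (B = 2000,
# seeded); no multiple-testing adjustment is applied anywhere.

#' Pearson chi-square for a 2x2 contingency table
#'
#' Uncorrected Pearson chi-square, sum of (O - E)^2 / E over the four cells.
#' Rows are groups and columns outcomes; all margins must be positive.
#'
#' @param a,b,c,d Cell counts, row-wise: the table is
#'   \code{rbind(c(a, b), c(c, d))}. Alternatively pass a 2x2 matrix as `a`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @examples
#' chi2_2x2(29, 10, 79, 144) # occluded-by-timeliness table
#' @export
chi2_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(a)) a else rbind(c(a, b), c(c, d))
  if (!all(dim(m) == c(2L, 2L))) abort("expected a 2x2 table")
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) abort("all margins must be positive")
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    n = sum(m)
  )
}

#' Goodness-of-fit chi-square against weighted expected counts
#'
#' Expected counts are the weights normalised to the observed total;
#' statistic is sum of (O - E)^2 / E.
#'
#' @param observed Non-negative integer counts.
#' @param expected_weights Non-negative weights, same length; at least one
#'   positive in every cell.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @export
chi2_gof <- function(observed, expected_weights = rep(1, length(observed))) {
  if (length(observed) != length(expected_weights)) {
    abort("observed and expected_weights must have the same length")
  }
  if (sum(observed) <= 0) abort("observed counts sum to zero")
  if (any(expected_weights <= 0)) abort("every expected cell must be positive")
  p <- expected_weights / sum(expected_weights)
  res <- suppressWarnings(chisq.test(observed, p = p))
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    n = sum(observed)
  )
}

#' Mann-Whitney U statistic
#'
#' U1 counts, over all (x, y) pairs, 1 when x > y and 0.5 for a tie; U2 is
#' the complement (U1 + U2 = n1 * n2). The conventional report is
#' min(U1, U2). Computed by the midrank formula, so ties are handled exactly.
#'
#' @param x,y Non-empty numeric samples.
#' @return A one-row tibble: `u` (min of the two), `u1`, `u2`, `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(rep(1, 6), 0), rep(1, 7)) # current-driver data: U = 21
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) abort("both samples must be non-empty")
  r <- rank(c(x, y)) # midranks
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  tibble::tibble(u = min(u1, u2), u1 = u1, u2 = u2, n1 = n1, n2 = n2)
}

#' Two-sample t test (pooled or Welch)
#'
#' @param x,y Samples, each with at least 2 observations.
#' @param variant `"pooled"` (classical equal-variance, df = n1 + n2 - 2) or
#'   `"welch"` (Satterthwaite fractional df).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_x`,
#'   `mean_y`.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) abort("each group needs n >= 2")
  if (var(x) == 0 && var(y) == 0) abort("zero variance in both groups")
  res <- t.test(x, y, var.equal = (variant == "pooled"))
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    mean_x = mean(x),
    mean_y = mean(y)
  )
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors, n >= 3, non-constant.
#' @return A one-row tibble: `r`, `n`, `statistic`, `df`, `p_value`.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for constant input")
  res <- cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(res$estimate),
    n = length(x),
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value
  )
}

#' Regression of log reaction time on occlusion time with subject effects
#'
#' Ordinary least squares of log reaction time on scotoma occlusion time plus
#' subject indicator contrasts (reference level: first participant
#' alphabetically). This is the within-subjects model for whether occlusion
#' predicts response latency over and above stable individual differences.
#' Reaction times are log transformed (natural log) because they are
#' right-skewed.
#'
#' @param table An `event_table` (or any data frame) with `log_rt`,
#'   `occlusion_time`, `participant_id`; rows with missing log RT are
#'   dropped.
#' @return An object of class `occlusion_rt_fit` wrapping the `lm` fit, with
#'   [tidy()] and [glance()] methods. Key quantities: the occlusion-time
#'   slope (log-seconds per second occluded) with its 95% CI, overall F and
#'   adjusted R-squared.
#' @export
ols_logrt <- function(table) {
  df <- table |>
    dplyr::filter(!is.na(.data$log_rt), !is.na(.data$occlusion_time)) |>
    dplyr::mutate(participant_id = factor(as.character(.data$participant_id),
                                          levels = sort(unique(as.character(.data$participant_id)))))
  n_sub <- nlevels(df$participant_id)
  if (nrow(df) <= n_sub + 1L) abort("not enough observations to fit the model")
  if (sd(df$occlusion_time) == 0) {
    abort("occlusion_time is constant: slope not identifiable (column occlusion_time aliased)")
  }
  fit <- if (n_sub > 1L) {
    lm(log_rt ~ occlusion_time + participant_id, data = df)
  } else {
    lm(log_rt ~ occlusion_time, data = df)
  }
  if (any(is.na(coef(fit)))) {
    abort(paste0("collinear design: aliased column(s) ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  ci <- suppressWarnings(confint(fit))["occlusion_time", ]
  structure(
    list(
      fit = fit,
      occ_slope = unname(coef(fit)["occlusion_time"]),
      occ_slope_ci = unname(ci),
      n = nrow(df),
      n_subjects = n_sub
    ),
    class = "occlusion_rt_fit"
  )
}

#' @export
print.occlusion_rt_fit <- function(x, ...) {
  g <- glance(x)
  cat("<occlusion_rt_fit>\n")
  cat(sprintf("  n = %d events, %d participants\n", x$n, x$n_subjects))
  cat(sprintf("  occlusion-time slope = %.3f log-s per s occluded (95%% CI %.3f to %.3f)\n",
              x$occ_slope, x$occ_slope_ci[1], x$occ_slope_ci[2]))
  cat(sprintf("  F(%d, %d) = %.2f, adjusted R^2 = %.3f\n",
              g$df, g$df_residual, g$statistic, g$adj_r_squared))
  invisible(x)
}

#' @export
tidy.occlusion_rt_fit <- function(x, conf.int = TRUE, ...) {
  s <- summary(x$fit)$coefficients
  out <- tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p_value = s[, "Pr(>|t|)"]
  )
  if (conf.int) {
    ci <- suppressWarnings(confint(x$fit))
    out$conf_low <- ci[, 1]
    out$conf_high <- ci[, 2]
  }
  out
}

#' @export
glance.occlusion_rt_fit <- function(x, ...) {
  s <- summary(x$fit)
  fstat <- s$fstatistic
  tibble::tibble(
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    statistic = unname(fstat[1]),
    df = as.integer(unname(fstat[2])),
    df_residual = as.integer(unname(fstat[3])),
    p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = x$n
  )
}

#' Untimely-reaction summary
#'
#' Proportions of untimely reactions by participant group, eccentricity
#' class and drive type, and the occlusion-by-timeliness 2x2 contingency
#' table over gaze-usable detected events (was the event ever occluded vs
#' was the reaction timely), with its uncorrected chi-square.
#'
#' @param table An `event_table`; a `group` column (e.g. CFL/NV) is used if
#'   present.
#' @return A list: `by_stratum` (tibble of proportions), `contingency`
#'   (2x2 matrix, rows untimely/timely, cols occluded/not), `test` (tibble
#'   from [chi2_2x2()], or `NULL` when a margin is empty).
#' @export
untimely_summary <- function(table) {
  det <- dplyr::filter(table, .data$detected, !is.na(.data$timely))
  strata <- intersect(c("group", "ecc_class", "drive_type"), names(det))
  by_stratum <- det |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::summarise(
      n = dplyr::n(),
      untimely = sum(!.data$timely),
      prop_untimely = mean(!.data$timely),
      .groups = "drop"
    )
  usable <- dplyr::filter(det, .data$gaze_usable)
  m <- NULL; test <- NULL
  if (nrow(usable) > 0) {
    occluded <- usable$occlusion_time > 0
    untimely <- !usable$timely
    m <- rbind(
      untimely = c(occluded = sum(untimely & occluded), clear = sum(untimely & !occluded)),
      timely = c(occluded = sum(!untimely & occluded), clear = sum(!untimely & !occluded))
    )
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) test <- chi2_2x2(m)
  }
  list(by_stratum = by_stratum, contingency = m, test = test)
}

#' Stratified median reaction times with bootstrap intervals
#'
#' Median reaction time per stratum with a percentile bootstrap 95%
#' confidence interval (B resamples, seeded for reproducibility). Undetected
#' events (missing RT) are excluded.
#'
#' @param table An `event_table` (or data frame with `reaction_time`).
#' @param by Character vector of stratifier columns (default none: one
#'   overall stratum).
#' @param B Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return A tibble: stratifiers, `n`, `median`, `ci_low`, `ci_high`,
#'   `mean`, `sd`.
#' @export
median_summary <- function(table, by = character(), B = 2000, conf = 0.95, seed = 1L) {
  det <- dplyr::filter(table, !is.na(.data$reaction_time))
  if (nrow(det) == 0L) abort("no detected events with reaction times")
  alpha <- (1 - conf) / 2
  boot_ci <- function(v, rng_seed) {
    if (length(v) == 1L) return(c(v, v))
    set.seed(rng_seed)
    meds <- replicate(B, median(sample(v, replace = TRUE)))
    unname(quantile(meds, c(alpha, 1 - alpha)))
  }
  grouped <- det |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_split()
  keys <- det |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_keys()
  res <- purrr::imap_dfr(grouped, function(g, i) {
    v <- g$reaction_time
    ci <- boot_ci(v, seed + i)
    tibble::tibble(
      n = length(v), median = median(v),
      ci_low = ci[1], ci_high = ci[2],
      mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_
    )
  })
  dplyr::bind_cols(keys, res)
}
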