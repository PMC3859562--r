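#' Kaplan-Meier estimate per group
#'
#' Product-limit survival curves for each label group, computed with
#' [survival::survfit()]. Returned in tidy long form, one row per distinct
#' time per group, suitable for direct plotting or TSV export.
#'
#' @param S a [surv_table()].
#' @param labels named vector (names = sample ids) or a data frame with
#'   columns `sample_id` and `label`, assigning each sample to a group.
#' @return A `km_curves` tibble with columns `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(S, labels) {
  lab <- normalize_labels(S, labels)
  df <- data.frame(time = S$time_months, event = S$event, group = lab)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (is.null(fit$strata)) {
    groups <- rep(as.character(unique(lab)), length(fit$time))
  } else {
    groups <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  structure(tibble(group = groups, time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, n_censor = fit$n.censor,
                   survival = fit$surv),
            class = c("km_curves", class(tibble())))
}

# Align labels to the survival table's sample order
normalize_labels <- function(S, labels) {
  if (is.data.frame(labels)) {
    labels <- setNames(labels$label, labels$sample_id)
  }
  if (!is.null(names(labels))) {
    missing <- setdiff(names(labels), S$sample_id)
    if (length(missing)) {
      abort(paste0("Label sample id(s) not in survival table: ",
                   paste(utils::head(missing, 3), collapse = ", ")))
    }
    if (!all(S$sample_id %in% names(labels))) {
      abort("Every survival-table sample needs a label.")
    }
    labels <- labels[S$sample_id]
  } else if (length(labels) != nrow(S)) {
    abort("Unnamed labels must match the survival table row-for-row.")
  }
  unname(labels)
}

#' @rdname km_estimate
#' @param object a `km_curves` tibble.
#' @param ... unused.
#' @method autoplot km_curves
#' @export
autoplot.km_curves <- function(object, ...) {
  start <- dplyr::distinct(as_tibble(object), .data$group) |>
    mutate(time = 0, survival = 1)
  df <- bind_rows(start,
                  as_tibble(object)[, c("group", "time", "survival")]) |>
    arrange(.data$group, .data$time)
  ggplot(df, aes(x = .data$time, y = .data$survival,
                 colour = factor(.data$group))) +
    geom_step() +
    labs(x = "Time (months)", y = "Metastasis-free survival",
         colour = "Group") +
    theme_minimal()
}

# Precompute the risk-set structure of a cohort once, so the two-group
# log-rank statistic can be re-evaluated cheaply for many candidate
# labelings (the cost function's inner loop).
logrank_context <- function(time, event) {
  n <- length(time)
  # events before censorings at tied times: censored-at-t are still at risk
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]
  ev_pos <- which(event == 1L)
  ev_time <- time[ev_pos]
  tid <- match(ev_time, unique(ev_time))        # tie-group id per event
  first <- ev_pos[!duplicated(tid)]             # first position of each tie
  nj <- n - first + 1L                          # total at risk per event time
  dj <- tabulate(tid)                           # total events per event time
  list(n = n, ord = ord, ev_pos = ev_pos, tid = tid,
       first = first, nj = nj, dj = dj)
}

# O-E / variance form of the two-group log-rank given 0/1 group labels
logrank_stat <- function(ctx, g) {
  gs <- g[ctx$ord]
  n1 <- sum(gs)
  if (n1 == 0L || n1 == ctx$n) return(NULL)
  if (length(ctx$ev_pos) == 0L) return(NULL)
  cum1 <- c(0L, cumsum(gs))
  n1j <- n1 - cum1[ctx$first]                   # group-1 at risk per event time
  d1j <- as.numeric(rowsum(gs[ctx$ev_pos], ctx$tid, reorder = FALSE))
  frac <- n1j / ctx$nj
  o_minus_e <- sum(d1j - ctx$dj * frac)
  denom <- ctx$nj - 1
  vterm <- ctx$dj * frac * (1 - frac) * (ctx$nj - ctx$dj) / pmax(denom, 1)
  vterm[denom <= 0] <- 0
  v <- sum(vterm)
  if (v <= 0) return(NULL)
  list(observed = sum(d1j), expected = sum(ctx$dj * frac),
       statistic = o_minus_e^2 / v, n1 = n1)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison of two survival curves, with
#' the hypergeometric variance and aggregated risk sets at tied event
#' times; the p-value is the chi-square(1) upper tail. The computation is
#' a vectorized in-package implementation (it is also the threshold
#' optimizer's inner loop); it is validated against
#' [survival::survdiff()] in the test suite.
#'
#' @param S a [surv_table()].
#' @param labels binary group membership (0/1), named by sample id or
#'   aligned with `S`; a `sample_id`/`label` data frame also works.
#' @return A `logrank_test` list: `statistic`, `df`, `p.value`,
#'   `group_sizes`, `event_counts`, `observed`, `expected` (group-1 side).
#' @export
logrank_test <- function(S, labels) {
  g <- as.integer(normalize_labels(S, labels))
  if (!all(g %in% c(0L, 1L))) abort("Labels must be binary (0/1).")
  if (sum(g) == 0L || sum(g) == length(g)) {
    abort("Both groups must be non-empty.")
  }
  if (sum(S$event) == 0L) abort("No events; log-rank test undefined.")
  ctx <- logrank_context(S$time_months, S$event)
  st <- logrank_stat(ctx, g)
  if (is.null(st)) abort("Degenerate risk sets; log-rank test undefined.")
  structure(list(statistic = st$statistic, df = 1L,
                 p.value = chi2_sf(st$statistic, 1L),
                 group_sizes = c(`0` = sum(g == 0L), `1` = sum(g == 1L)),
                 event_counts = c(`0` = sum(S$event[g == 0L]),
                                  `1` = sum(S$event[g == 1L])),
                 observed = st$observed, expected = st$expected),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @method tidy logrank_test
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         n0 = unname(x$group_sizes[1]), n1 = unname(x$group_sizes[2]),
         events0 = unname(x$event_counts[1]),
         events1 = unname(x$event_counts[2]))
}

#' @method glance logrank_test
#' @export
glance.logrank_test <- function(x, ...) tidy(x)[, c("statistic", "df", "p.value")]

#' Chi-square upper-tail probability
#'
#' Survival function of the chi-square distribution, the reference
#' distribution for log-rank and likelihood-ratio statistics. Underflowing
#' p-values are reported as the smallest positive double with an
#' `underflow` attribute rather than truncated to 0.
#'
#' @param x non-negative statistic.
#' @param df degrees of freedom (>= 1).
#' @return Upper-tail probability in (0, 1].
#' @export
chi2_sf <- function(x, df) {
  if (!is.numeric(x) || any(x < 0)) abort("`x` must be non-negative.")
  if (df < 1) abort("`df` must be >= 1.")
  p <- pchisq(x, df = df, lower.tail = FALSE)
  if (any(p == 0)) {
    p[p == 0] <- .Machine$double.xmin
    attr(p, "underflow") <- TRUE
  }
  p
}

#' Cohort-stability test for two BPMS-positive proportions
#'
#' Pearson chi-square on the 2x2 table of positive/negative counts in two
#' cohorts, with the Yates continuity correction (|O-E| reduced by 0.5),
#' df = 1 — the convention under which the published cross-cohort
#' comparison (35/871 vs 6/341 positives) gives chi2 = 3.1657, p = 0.0752.
#'
#' @param m1,N1 positives and total in cohort 1.
#' @param m2,N2 positives and total in cohort 2.
#' @return A tibble with `statistic`, `df`, `p.value`.
#' @export
proportion_stability_test <- function(m1, N1, m2, N2) {
  if (N1 <= 0 || N2 <= 0 || m1 < 0 || m2 < 0 || m1 > N1 || m2 > N2) {
    abort("Counts must satisfy 0 <= m <= N with N > 0.")
  }
  tab <- matrix(c(m1, N1 - m1, m2, N2 - m2), nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0)) {
    abort("Degenerate 2x2 table: an outcome margin is empty.")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = TRUE))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = unname(ht$p.value))
}

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial-likelihood fit with Efron handling of tied event
#' times, via [survival::coxph()]. With zero covariates, returns the
#' null-model baseline: just the partial log-likelihood.
#'
#' @param S a [surv_table()].
#' @param covariates data frame of per-sample covariates aligned with `S`
#'   (or carrying a `sample_id` column), possibly zero columns.
#' @return A `bpms_cox` object wrapping the fit; see [tidy()]/[glance()].
#' @export
cox_fit <- function(S, covariates = NULL) {
  if (sum(S$event) == 0L) abort("No events; Cox model undefined.")
  if (is.null(covariates)) covariates <- S[, integer(0)]
  covariates <- as.data.frame(covariates)
  if ("sample_id" %in% names(covariates)) {
    i <- match(S$sample_id, covariates$sample_id)
    if (anyNA(i)) abort("Covariate table is missing some samples.")
    covariates <- covariates[i, setdiff(names(covariates), "sample_id"),
                             drop = FALSE]
  }
  if (ncol(covariates) > 0) {
    if (nrow(covariates) != nrow(S)) {
      abort("Covariates must align with the survival table.")
    }
    num <- covariates[vapply(covariates, is.numeric, logical(1))]
    if (ncol(num) > 1 && anyDuplicated(t(as.matrix(num)))) {
      abort("Collinear duplicate covariate columns.")
    }
  }
  df <- cbind(data.frame(.time = S$time_months, .event = S$event), covariates)
  if (ncol(covariates) == 0L) {
    fit <- survival::coxph(survival::Surv(.time, .event) ~ 1, data = df,
                           ties = "efron")
  } else {
    fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                           ties = "efron")
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      abort(paste0("Cox fit failed to estimate: ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(list(fit = fit,
                 loglik = fit$loglik[length(fit$loglik)],
                 loglik_null = fit$loglik[1],
                 n = fit$n, nevent = fit$nevent),
            class = "bpms_cox")
}

#' @export
print.bpms_cox <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d, partial logLik = %.3f\n",
              x$n, x$nevent, x$loglik))
  if (!is.null(stats::coef(x$fit)) && length(stats::coef(x$fit))) {
    print(tidy(x))
  }
  invisible(x)
}

#' @method tidy bpms_cox
#' @export
tidy.bpms_cox <- function(x, conf.level = 0.95, ...) {
  cf <- stats::coef(x$fit)
  if (is.null(cf) || length(cf) == 0L) {
    return(tibble(term = character(), estimate = numeric(),
                  hazard_ratio = numeric(), conf.low = numeric(),
                  conf.high = numeric(), p.value = numeric()))
  }
  se <- sqrt(diag(x$fit$var))
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble(term = names(cf),
         estimate = unname(cf),
         std.error = se,
         hazard_ratio = exp(unname(cf)),
         conf.low = exp(unname(cf) - z * se),
         conf.high = exp(unname(cf) + z * se),
         p.value = 2 * stats::pnorm(-abs(unname(cf) / se)))
}

#' @method glance bpms_cox
#' @export
glance.bpms_cox <- function(x, ...) {
  tibble(logLik = x$loglik, logLik_null = x$loglik_null,
         n = x$n, nevent = x$nevent,
         df = length(stats::coef(x$fit)))
}

#' Likelihood-ratio test between nested Cox models
#'
#' Compares a reduced model's partial log-likelihood `L0` with a full
#' model's `L1` (the reduced model plus `df` extra covariates):
#' statistic = -2 (L0 - L1), referred to chi-square(`df`). This is the
#' ANOVA step used to ask whether the BPMS adds prognostic information on
#' top of clinical factors or other signatures.
#'
#' @param L0 reduced-model partial log-likelihood.
#' @param L1 full-model partial log-likelihood (must be >= L0).
#' @param df number of added parameters (>= 1).
#' @return A tibble with `statistic`, `df`, `p.value`.
#' @export
nested_lrt <- function(L0, L1, df = 1L) {
  if (!is.finite(L0) || !is.finite(L1)) abort("Log-likelihoods must be finite.")
  if (df < 1) abort("`df` must be >= 1.")
  if (L1 < L0 - 1e-9) {
    abort("L1 < L0: models are not nested or the full fit did not converge.")
  }
  stat <- max(0, -2 * (L0 - L1))
  tibble(statistic = stat, df = as.integer(df),
         p.value = as.numeric(chi2_sf(stat, df)))
}
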