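#' Cost-function configuration
#'
#' The threshold search minimizes `C(tau) = alpha(p) + beta(m, N)` where
#' `p` is the log-rank p-value of the candidate BPMS-positive cohort, `m`
#' its size and `N` the total cohort size. `alpha(p) = ceiling(log_b p)`
#' is a discretized significance term (integer steps, base `alpha_base`),
#' and `beta(m, N) = -w * m / N` rewards larger cohorts, with `w` scaled
#' so typical cohort fractions span the same range as `alpha`. The
#' discreteness makes the cost deliberately frugal: adding a patient or
#' two barely moves it, while a decade jump in the p-value moves it by a
#' whole unit. Degenerate labelings (empty or full cohort, or no events
#' in a group) earn a flat penalty.
#'
#' @param w cohort-size weight (> 0); default 50 so fractions of 0-10%
#'   span roughly 0 to -5.
#' @param alpha_base logarithm base of the significance discretization.
#' @param penalty cost assigned to degenerate cohorts.
#' @param min_cohort smallest non-degenerate BPMS-positive cohort size.
#' @param max_fraction largest admissible BPMS-positive cohort fraction;
#'   the signature describes a minority high-risk subpopulation (observed
#'   whole-cohort positive fractions are 2-5%), so candidate cohorts above
#'   this bound are treated as degenerate. Also keeps the range of `beta`
#'   (0 to -w * max_fraction) commensurate with `alpha`.
#' @param p_floor significance floor: p-values below it are clamped before
#'   discretization, so `alpha` saturates and stops rewarding ever-more
#'   extreme significance. Without a floor the search collapses onto tiny
#'   overfit cohorts whose extreme training p-values never generalize;
#'   the floor is the anti-overfitting counterpart of `beta`.
#' @param retain_p significance cutoff used when retaining candidate
#'   solutions during training.
#' @param cv_censor_months right-censoring horizon applied to the
#'   cross-validation half (training halves stay uncensored).
#' @param maxit Nelder-Mead iteration cap per simplex run.
#' @param n_hops seeded perturbation restarts around the incumbent within
#'   one [optimize_once()] call. The cost is piecewise constant, so a
#'   single simplex stalls on plateaus; re-launching it from small random
#'   perturbations of the best point (a basin-hopping refinement, kept
#'   deterministic under the run's seed) lets each restart descend
#'   several plateau levels.
#' @param hop_scale standard deviation (z-units) of the hop perturbation.
#' @return A `cost_config` list.
#' @export
cost_config <- function(w = 50, alpha_base = 10, penalty = 10,
                        min_cohort = 1L, max_fraction = 0.10,
                        p_floor = 1e-4, retain_p = 0.05,
                        cv_censor_months = 60, maxit = 500L,
                        n_hops = 12L, hop_scale = 0.3) {
  if (w <= 0) abort("`w` must be positive.")
  if (alpha_base <= 1) abort("`alpha_base` must exceed 1.")
  if (max_fraction <= 0 || max_fraction > 1) {
    abort("`max_fraction` must lie in (0, 1].")
  }
  if (p_floor <= 0 || p_floor > 1) abort("`p_floor` must lie in (0, 1].")
  structure(list(w = w, alpha_base = alpha_base, penalty = penalty,
                 min_cohort = as.integer(min_cohort),
                 max_fraction = max_fraction, p_floor = p_floor,
                 retain_p = retain_p,
                 cv_censor_months = cv_censor_months,
                 maxit = as.integer(maxit), n_hops = as.integer(n_hops),
                 hop_scale = hop_scale),
            class = "cost_config")
}

# Bundle features + survival + precomputed log-rank risk sets so the cost
# can be evaluated ~10^5 times per training run without re-sorting.
cost_context <- function(features, S, cfg) {
  i <- match(colnames(features), S$sample_id)
  if (anyNA(i)) abort("Every feature column needs a survival record.")
  S <- S[i, ]
  list(features = features, S = S, cfg = cfg,
       lr = logrank_context(S$time_months, S$event),
       n = ncol(features), events = S$event,
       total_events = sum(S$event))
}

cost_eval <- function(tau, ctx, sig) {
  act <- activation_matrix(ctx$features, tau, sig)
  g <- as.integer(colSums(act) == nrow(sig))
  m <- sum(g)
  if (m < ctx$cfg$min_cohort || m > ctx$cfg$max_fraction * ctx$n) {
    return(list(cost = ctx$cfg$penalty, m = m, p = NA_real_))
  }
  ev1 <- sum(ctx$events[g == 1L])
  if (ev1 == 0L || ev1 == ctx$total_events) {
    return(list(cost = ctx$cfg$penalty, m = m, p = NA_real_))
  }
  st <- logrank_stat(ctx$lr, g)
  if (is.null(st)) return(list(cost = ctx$cfg$penalty, m = m, p = NA_real_))
  p <- as.numeric(chi2_sf(st$statistic, 1L))
  a <- ceiling(log(max(p, ctx$cfg$p_floor), base = ctx$cfg$alpha_base))
  b <- -ctx$cfg$w * m / ctx$n
  list(cost = a + b, m = m, p = p)
}

#' Evaluate the threshold cost function
#'
#' Classifies the cohort at thresholds `tau` and scores the resulting
#' BPMS-positive cohort; lower is better. See [cost_config()] for the
#' functional form.
#'
#' @param tau threshold vector (one per signature component).
#' @param features components x samples matrix.
#' @param S a [surv_table()] covering the samples.
#' @param sig a [signature_def()].
#' @param cfg a [cost_config()].
#' @return A one-row tibble: `cost`, `cohort_size`, `p.value`.
#' @export
cost <- function(tau, features, S, sig, cfg = cost_config()) {
  if (!all(is.finite(tau))) abort("Thresholds must be finite.")
  ctx <- cost_context(features, S, cfg)
  r <- cost_eval(tau, ctx, sig)
  tibble(cost = r$cost, cohort_size = r$m, p.value = r$p)
}

#' One seeded Nelder-Mead threshold optimization
#'
#' Draws a standard-normal starting threshold vector from `seed` and
#' minimizes the cost with [stats::optim()]'s Nelder-Mead implementation.
#' Because the cost is piecewise constant in `tau`, single runs settle on
#' local plateaus; the training protocol relies on many restarts rather
#' than on any one run.
#'
#' @param features components x samples matrix.
#' @param S a [surv_table()].
#' @param sig a [signature_def()].
#' @param cfg a [cost_config()].
#' @param seed integer seed for the starting point.
#' @return A one-row tibble: seed, per-component thresholds (`tau_*`),
#'   `cost`, `cohort_size`, `p.value`, `converged`.
#' @export
optimize_once <- function(features, S, sig, cfg = cost_config(), seed = 1L) {
  ctx <- cost_context(features, S, cfg)
  optimize_once_ctx(ctx, sig, seed)
}

optimize_once_ctx <- function(ctx, sig, seed) {
  set.seed(seed)
  cfg <- ctx$cfg
  start <- rnorm(nrow(sig))
  fn <- function(tau) cost_eval(tau, ctx, sig)$cost
  # a start on the degenerate plateau gives the simplex nothing to work
  # with; contract it toward 0 (where cohorts are non-empty) until the
  # cost is informative
  k <- 0L
  while (fn(start) >= cfg$penalty && k < 10L) {
    start <- start * 0.7
    k <- k + 1L
  }
  nm <- function(par) {
    tryCatch(optim(par, fn, method = "Nelder-Mead",
                   control = list(maxit = cfg$maxit, reltol = 1e-10)),
             error = function(e) NULL)
  }
  res <- nm(start)
  if (is.null(res)) {
    tau <- start; converged <- FALSE
  } else {
    tau <- res$par
    best <- res$value
    converged <- TRUE
    for (h in seq_len(cfg$n_hops)) {
      res_h <- nm(tau + cfg$hop_scale * rnorm(nrow(sig)))
      if (!is.null(res_h) && res_h$value < best) {
        best <- res_h$value
        tau <- res_h$par
      }
    }
  }
  final <- cost_eval(tau, ctx, sig)
  out <- tibble(seed = as.integer(seed), cost = final$cost,
                cohort_size = final$m, p.value = final$p,
                converged = converged && is.finite(final$cost))
  taus <- as.list(setNames(tau, paste0("tau_", sig$name)))
  dplyr::bind_cols(out, as_tibble(taus))
}

tau_columns <- function(df, sig) {
  as.matrix(df[, paste0("tau_", sig$name), drop = FALSE])
}

#' Train signature thresholds by optimize / cross-validate / average
#'
#' The full threshold-selection protocol: split the cohort into two
#' near-equal halves (train and cross-validation), run `n_restarts`
#' seeded Nelder-Mead optimizations on the training half (uncensored
#' survival), evaluate every candidate solution's log-rank p-value on
#' both halves (the CV half right-censored at `cfg$cv_censor_months`),
#' retain solutions significant (`p < cfg$retain_p`) in *both*, and
#' average the retained threshold vectors per component to produce the
#' final signature.
#'
#' @param X an [expr_matrix()]; raw input is median-centered and z-scored
#'   first.
#' @param S a [surv_table()] (uncensored; censoring is handled per half).
#' @param sig a [signature_def()].
#' @param specs named list of [metagene_spec()].
#' @param cfg a [cost_config()].
#' @param n_restarts number of seeded optimizations.
#' @param split_seed seed for the half-split and the restart seed stream.
#' @return A `trained_signature` list: `thresholds` (final averaged
#'   vector, NA if nothing retained), `n_candidates`, `n_retained`,
#'   `results` (per-restart tibble with train/CV p-values and sizes),
#'   `retention` criteria, `success` flag.
#' @export
train_signature <- function(X, S, sig, specs, cfg = cost_config(),
                            n_restarts = 100L, split_seed = 1L) {
  if (ncol(X) < 40L) abort("Too few samples: need >= 40.")
  if (sum(S$event) < 10L) abort("Too few events: need >= 10.")
  if (norm_state(X) == "raw_summarized") {
    X <- zscore_genes(median_center_samples(X))
  }
  features <- assemble_feature_matrix(X, sig, specs)
  # canonical sample order so the split depends on ids, not input order
  features <- features[, order(colnames(features)), drop = FALSE]
  set.seed(split_seed)
  n <- ncol(features)
  idx <- sample.int(n)
  tr <- sort(idx[seq_len(floor(n / 2))])
  cv <- sort(idx[(floor(n / 2) + 1):n])
  S_tr <- surv_table(S[match(colnames(features)[tr], S$sample_id), ])
  S_cv <- right_censor(
    surv_table(S[match(colnames(features)[cv], S$sample_id), ]),
    cfg$cv_censor_months)
  ctx_tr <- cost_context(features[, tr, drop = FALSE], S_tr, cfg)
  ctx_cv <- cost_context(features[, cv, drop = FALSE], S_cv, cfg)
  seeds <- split_seed * 1000L + seq_len(n_restarts)
  results <- purrr::map_dfr(seeds, function(s) optimize_once_ctx(ctx_tr, sig, s))
  eval_half <- function(tau, ctx) {
    r <- cost_eval(tau, ctx, sig)
    c(p = if (is.na(r$p)) 1 else r$p, m = r$m)
  }
  taus <- tau_columns(results, sig)
  cvres <- t(apply(taus, 1L, eval_half, ctx = ctx_cv))
  results$cv_p <- cvres[, "p"]
  results$cv_cohort_size <- as.integer(cvres[, "m"])
  results$train_p <- ifelse(is.na(results$p.value), 1, results$p.value)
  results$retained <- results$train_p < cfg$retain_p &
    results$cv_p < cfg$retain_p
  n_ret <- sum(results$retained)
  if (n_ret > 0) {
    thresholds <- colMeans(taus[results$retained, , drop = FALSE])
    thresholds <- threshold_vector(setNames(unname(thresholds), sig$name), sig)
  } else {
    thresholds <- setNames(rep(NA_real_, nrow(sig)), sig$name)
  }
  retained_frac <- n_ret / n_restarts
  if (retained_frac < 0.05) {
    warn(sprintf("Only %d/%d solutions retained (%.1f%%): the signature is unstable on this cohort.",
                 n_ret, n_restarts, 100 * retained_frac))
  }
  structure(list(thresholds = thresholds,
                 n_candidates = n_restarts,
                 n_retained = n_ret,
                 results = results,
                 signature = sig,
                 retention = list(p = cfg$retain_p,
                                  cv_censor_months = cfg$cv_censor_months),
                 train_samples = colnames(features)[tr],
                 cv_samples = colnames(features)[cv],
                 success = n_ret > 0),
            class = "trained_signature")
}

#' @export
print.trained_signature <- function(x, ...) {
  cat(sprintf("<trained_signature> %d/%d solutions retained (p < %g in train and CV)\n",
              x$n_retained, x$n_candidates, x$retention$p))
  if (x$success) print(round(x$thresholds, 4))
  else cat("Training failed: no solution was significant in both halves.\n")
  invisible(x)
}

#' @method tidy trained_signature
#' @export
tidy.trained_signature <- function(x, ...) {
  tibble(component = names(x$thresholds),
         threshold = unname(x$thresholds),
         direction = x$signature$direction)
}

#' @method glance trained_signature
#' @export
glance.trained_signature <- function(x, ...) {
  tibble(n_candidates = x$n_candidates, n_retained = x$n_retained,
         retained_fraction = x$n_retained / x$n_candidates,
         success = x$success)
}

#' Threshold distribution of retained solutions
#' @param object a `trained_signature`.
#' @param ... unused.
#' @method autoplot trained_signature
#' @export
autoplot.trained_signature <- function(object, ...) {
  df <- as_tibble(tau_columns(object$results, object$signature)) |>
    mutate(retained = object$results$retained) |>
    tidyr::pivot_longer(-"retained", names_to = "component",
                        values_to = "threshold")
  ggplot(dplyr::filter(df, .data$retained),
         aes(x = .data$threshold)) +
    geom_density() +
    facet_wrap(~component, scales = "free") +
    labs(title = "Retained threshold solutions", x = "Threshold (z-units)") +
    theme_minimal()
}

#' Compare optimized against random threshold solutions
#'
#' The optimization control experiment: arm A runs `n_opt` seeded
#' optimizations; arm B evaluates `n_rand` random standard-normal
#' threshold vectors without optimization. Each run records the
#' BPMS-positive cohort's log-rank p-value and size; Welch t-tests
#' compare the two arms on both metrics. Runs whose cohort is degenerate
#' (no testable stratification) are scored as non-significant (p = 1),
#' mirroring how failed panels are scored in the Monte-Carlo null.
#'
#' @param features components x samples matrix.
#' @param S a [surv_table()].
#' @param sig a [signature_def()].
#' @param cfg a [cost_config()].
#' @param n_opt,n_rand runs per arm (>= 30 each).
#' @param seed integer seed.
#' @return A `signature_comparison` list: `runs` tibble (arm, p, size),
#'   `summary` tibble (per-arm mean/variance of both metrics),
#'   `p_value_test` and `cohort_size_test` (Welch t-test results).
#' @export
compare_optimized_vs_random <- function(features, S, sig,
                                        cfg = cost_config(),
                                        n_opt = 100L, n_rand = 100L,
                                        seed = 1L) {
  if (n_opt < 30L || n_rand < 30L) abort("Both arms need >= 30 runs.")
  ctx <- cost_context(features, S, cfg)
  opt <- purrr::map_dfr(seed * 1000L + seq_len(n_opt),
                        function(s) optimize_once_ctx(ctx, sig, s)) |>
    mutate(arm = "optimized")
  set.seed(seed * 1000L + n_opt + 1L)
  rand <- purrr::map_dfr(seq_len(n_rand), function(i) {
    tau <- rnorm(nrow(sig))
    r <- cost_eval(tau, ctx, sig)
    tibble(seed = NA_integer_, cost = r$cost, cohort_size = r$m,
           p.value = r$p, converged = NA)
  }) |> mutate(arm = "random")
  runs <- bind_rows(opt[, c("arm", "p.value", "cohort_size")],
                    rand[, c("arm", "p.value", "cohort_size")])
  if (all(is.na(runs$p.value[runs$arm == "optimized"])) ||
      all(is.na(runs$p.value[runs$arm == "random"]))) {
    abort("An arm produced only degenerate cohorts; comparison undefined.")
  }
  runs$p.value[is.na(runs$p.value)] <- 1
  summary <- runs |>
    group_by(.data$arm) |>
    summarise(mean_p = mean(.data$p.value),
              var_p = var(.data$p.value),
              mean_cohort = mean(.data$cohort_size),
              var_cohort = var(.data$cohort_size),
              n_runs = dplyr::n(), .groups = "drop")
  tt_p <- t.test(p.value ~ arm, data = runs)
  tt_m <- t.test(cohort_size ~ arm, data = runs)
  structure(list(runs = runs, summary = summary,
                 p_value_test = tt_p, cohort_size_test = tt_m),
            class = "signature_comparison")
}

#' @export
print.signature_comparison <- function(x, ...) {
  cat("Optimized vs random threshold solutions\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat(sprintf("Welch t (log-rank p): p = %.3g; Welch t (cohort size): p = %.3g\n",
              x$p_value_test$p.value, x$cohort_size_test$p.value))
  invisible(x)
}

#' @method glance signature_comparison
#' @export
glance.signature_comparison <- function(x, ...) {
  s <- x$summary
  o <- s[s$arm == "optimized", ]; r <- s[s$arm == "random", ]
  tibble(mean_p_optimized = o$mean_p, mean_p_random = r$mean_p,
         mean_cohort_optimized = o$mean_cohort,
         mean_cohort_random = r$mean_cohort,
         t_test_p_pvalues = x$p_value_test$p.value,
         t_test_p_cohort = x$cohort_size_test$p.value)
}

#' @rdname compare_optimized_vs_random
#' @param object a `signature_comparison`.
#' @param ... unused.
#' @method autoplot signature_comparison
#' @export
autoplot.signature_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(object$runs, c("p.value", "cohort_size"),
                            names_to = "metric")
  ggplot(df, aes(x = .data$value, colour = .data$arm)) +
    geom_density() +
    facet_wrap(~metric, scales = "free") +
    labs(x = NULL, colour = NULL) +
    theme_minimal()
}

#' Random-signature Monte-Carlo null
#'
#' Asks whether the signature's gene list matters: draws `k_sets` random
#' panels of genes from the expression matrix, pushes each through the
#' identical train/cross-validate/average protocol, evaluates each
#' trained random signature's log-rank p-value on a held-out test cohort,
#' and reports the fraction of panels doing at least as well as the
#' reference signature (smaller p). Panels whose training retains no
#' solution are scored non-significant (p = 1). In structured mode
#' (default) each random panel mirrors the BPMS layout — 5 singleton
#' slots plus pseudo-meta-genes of 12 and 13 random genes; otherwise all
#' slots are singletons.
#'
#' @param X_train,S_train training cohort (expression + survival).
#' @param X_test,S_test held-out evaluation cohort.
#' @param reference_p the reference signature's log-rank p-value on the
#'   test cohort.
#' @param sig a [signature_def()] giving the slot layout (directions are
#'   reused slot-for-slot).
#' @param cfg a [cost_config()].
#' @param k_sets number of random panels (>= 20).
#' @param n_restarts optimizations per panel.
#' @param structured mirror the metagene structure (default TRUE).
#' @param seed integer seed.
#' @return A list: `percentile` (empirical fraction), `panel_p` (vector
#'   of test p-values), `n_failed` (panels with no retained solution).
#' @export
random_signature_null <- function(X_train, S_train, X_test, S_test,
                                  reference_p, sig, cfg = cost_config(),
                                  k_sets = 20L, n_restarts = 25L,
                                  structured = TRUE, seed = 1L) {
  if (k_sets < 20L) abort("`k_sets` must be >= 20.")
  n_slots <- nrow(sig)
  sizes <- if (structured) {
    k <- vapply(sig$name, function(nm) {
      if (sig$kind[match(nm, sig$name)] == "metagene") NA_integer_ else 1L
    }, integer(1))
    # pseudo-metagene sizes mirror the published 12- and 13-gene lists
    meta_sizes <- c(12L, 13L)
    k[is.na(k)] <- meta_sizes[seq_len(sum(is.na(k)))]
    k
  } else rep(1L, n_slots)
  pool <- intersect(rownames(X_train), rownames(X_test))
  need <- sum(sizes)
  if (length(pool) < need * 10L) {
    abort(sprintf("Need >= %d shared genes in the pool; found %d.",
                  need * 10L, length(pool)))
  }
  if (norm_state(X_test) == "raw_summarized") {
    X_test <- zscore_genes(median_center_samples(X_test))
  }
  panel_p <- numeric(k_sets)
  n_failed <- 0L
  for (b in seq_len(k_sets)) {
    set.seed(seed * 10000L + b)
    genes <- sample(pool, need)
    splits <- split(genes, rep(seq_len(n_slots), times = sizes))
    rand_sig <- signature_def(tibble(
      name = paste0("slot", seq_len(n_slots)),
      kind = ifelse(sizes > 1L, "metagene", "gene"),
      direction = sig$direction))
    rand_sig$name[sizes == 1L] <- vapply(splits[sizes == 1L], `[`,
                                         character(1), 1L)
    specs <- list()
    for (j in which(sizes > 1L)) {
      specs[[rand_sig$name[j]]] <- metagene_spec(rand_sig$name[j],
                                                 splits[[j]])
    }
    trained <- tryCatch(
      suppressWarnings(train_signature(X_train, S_train, rand_sig, specs,
                                       cfg, n_restarts,
                                       split_seed = seed * 10000L + b)),
      error = function(e) NULL)
    if (is.null(trained) || !trained$success) {
      n_failed <- n_failed + 1L
      panel_p[b] <- 1
      next
    }
    feats <- assemble_feature_matrix(X_test, rand_sig, specs)
    lab <- classify(feats, trained$thresholds, rand_sig)
    panel_p[b] <- tryCatch(
      logrank_test(S_test, setNames(lab$label, lab$sample_id))$p.value,
      error = function(e) 1)
  }
  list(percentile = mean(panel_p <= reference_p),
       panel_p = panel_p, n_failed = n_failed)
}
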