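canon <- canonical_bpms()

# one-component signature for controlled cost arithmetic
uni_sig <- signature_def(tibble::tibble(name = "G1", kind = "gene",
                                        direction = 1))

test_that("cost equals the discretized-significance plus cohort-size form", {
  set.seed(21)
  cfg <- cost_config(max_fraction = 0.5)
  for (i in 1:10) {
    n <- 80
    x <- rnorm(n)
    features <- matrix(x, nrow = 1, dimnames = list("G1", sprintf("c%03d", 1:n)))
    time <- rexp(n, 0.02 * ifelse(x > 0.5, 3, 1))
    S <- mk_surv(pmin(time, 60), as.integer(time <= 60),
                 ids = colnames(features))
    tau <- rnorm(1)
    got <- cost(tau, features, S, uni_sig, cfg)
    g <- as.integer(x > tau)
    m <- sum(g)
    if (m < 1 || m > 40 ||
        sum(S$event[g == 1]) == 0 || sum(S$event[g == 0]) == 0) {
      expect_equal(got$cost, cfg$penalty)
    } else {
      p_ref <- survival::survdiff(
        survival::Surv(S$time_months, S$event) ~ g)
      p_ref <- pchisq(p_ref$chisq, 1, lower.tail = FALSE)
      expect_equal(got$cost,
                   ceiling(log10(max(p_ref, cfg$p_floor))) - cfg$w * m / n,
                   tolerance = 1e-9)
      expect_equal(got$p.value, p_ref, tolerance = 1e-9)
      expect_equal(got$cohort_size, m)
    }
  }
  expect_error(cost(NaN, matrix(0, 1, 2, dimnames = list("G1", c("a", "b"))),
                    mk_surv(c(1, 2), c(1, 0), c("a", "b")), uni_sig, cfg),
               "finite")
})

test_that("the size term moves by one patient steps and alpha by decades", {
  cfg <- cost_config()
  # alpha component: p just above vs below a decade boundary
  expect_equal(ceiling(log10(0.011)), -1)
  a_above <- ceiling(log10(0.009))
  expect_equal(a_above, -2)
  # one extra patient changes beta by exactly -w/n
  n <- 500
  b1 <- -cfg$w * 10 / n
  b2 <- -cfg$w * 11 / n
  expect_equal(b2 - b1, -cfg$w / n)
})

test_that("optimization is deterministic, descends, and recovers planted cohorts", {
  sc <- fig1_scenario(seed = 3)
  cfg <- cost_config()
  r1 <- optimize_once(sc$features, sc$survival, sc$signature, cfg, seed = 17)
  r2 <- optimize_once(sc$features, sc$survival, sc$signature, cfg, seed = 17)
  expect_identical(r1, r2)

  # final cost never exceeds the cost at the seeded starting point
  for (s in c(2, 5, 8, 13)) {
    r <- optimize_once(sc$features, sc$survival, sc$signature, cfg, seed = s)
    set.seed(s)
    start <- rnorm(7)
    c0 <- cost(start, sc$features, sc$survival, sc$signature, cfg)$cost
    taus <- as.numeric(r[paste0("tau_", sc$signature$name)])
    cf <- cost(taus, sc$features, sc$survival, sc$signature, cfg)$cost
    expect_lte(cf, c0)
    expect_equal(cf, r$cost)
  }

  # on a strongly separated instance most restarts overlap the planted set
  ez <- easy_recovery_scenario(seed = 4)
  planted <- which(ez$truth$planted == 1)
  hits <- 0
  n_restarts <- 30
  for (s in seq_len(n_restarts)) {
    r <- optimize_once(ez$features, ez$survival, ez$signature, cfg,
                       seed = 100 + s)
    taus <- as.numeric(r[paste0("tau_", ez$signature$name)])
    lab <- classify(ez$features, taus, ez$signature)
    pos <- which(lab$label == 1)
    jac <- length(intersect(pos, planted)) /
      max(1, length(union(pos, planted)))
    hits <- hits + (jac >= 0.5)
  }
  expect_gte(hits / n_restarts, 0.5)
})

test_that("training retains only doubly significant solutions and averages them", {
  ez <- easy_recovery_scenario(seed = 6)
  tr <- suppressWarnings(
    train_signature(ez$cohort$expression, ez$survival, ez$signature,
                    ez$metagenes, cost_config(), n_restarts = 40,
                    split_seed = 6))
  expect_true(tr$success)
  res <- tr$results
  expect_true(all(res$train_p[res$retained] < 0.05))
  expect_true(all(res$cv_p[res$retained] < 0.05))
  expect_true(all(!res$retained |
                    (res$train_p < 0.05 & res$cv_p < 0.05)))
  kept <- res[res$retained, paste0("tau_", ez$signature$name)]
  expect_equal(unname(tr$thresholds), unname(colMeans(as.matrix(kept))),
               tolerance = 1e-12)

  # too-small inputs are rejected
  tiny <- generate_cohort(synthetic_config(n_samples = 10, seed = 1))
  expect_error(train_signature(tiny$expression, tiny$survival,
                               ez$signature, ez$metagenes),
               "Too few samples")
})

test_that("training is invariant to sample order and flags null cohorts unstable", {
  ez <- easy_recovery_scenario(seed = 8)
  X <- ez$cohort$expression
  tr1 <- suppressWarnings(
    train_signature(X, ez$survival, ez$signature, ez$metagenes,
                    cost_config(), n_restarts = 15, split_seed = 8))
  perm <- sample(ncol(X))
  Xp <- expr_matrix(unclass(X)[, perm], norm_state(X))
  Sp <- surv_table(as.data.frame(ez$survival)[perm, ])
  tr2 <- suppressWarnings(
    train_signature(Xp, Sp, ez$signature, ez$metagenes,
                    cost_config(), n_restarts = 15, split_seed = 8))
  expect_equal(tr1$thresholds, tr2$thresholds)

  # no planted signal: few solutions survive cross-validation and the
  # pipeline warns about instability
  null_co <- generate_cohort(synthetic_config(n_samples = 160, delta = 0,
                                              hazard_ratio = 1, seed = 5))
  expect_warning(
    tr_null <- train_signature(null_co$expression, null_co$survival,
                               ez$signature, ez$metagenes, cost_config(),
                               n_restarts = 60, split_seed = 5),
    "unstable")
  expect_lt(tr_null$n_retained / tr_null$n_candidates, 0.05)
})

test_that("the comparison summary reports both metrics for both arms", {
  sc <- fig1_scenario(seed = 2)
  cmp <- compare_optimized_vs_random(sc$features, sc$survival,
                                     sc$signature, cost_config(),
                                     n_opt = 30, n_rand = 30, seed = 2)
  expect_setequal(cmp$summary$arm, c("optimized", "random"))
  expect_true(all(c("mean_p", "var_p", "mean_cohort", "var_cohort") %in%
                    names(cmp$summary)))
  expect_true(all(is.finite(cmp$summary$mean_p)))
  expect_true(all(cmp$runs$p.value >= 0 & cmp$runs$p.value <= 1))
  expect_error(compare_optimized_vs_random(sc$features, sc$survival,
                                           sc$signature, cost_config(),
                                           n_opt = 5, n_rand = 30),
               "30")
})

test_that("the random-signature null scores boundaries correctly", {
  cfg2 <- synthetic_config(n_samples = 200, n_background_genes = 400,
                           delta = 0, hazard_ratio = 1, seed = 12)
  co <- generate_cohort(cfg2)
  X <- co$expression
  sel <- seq_len(100)
  Xtr <- expr_matrix(unclass(X)[, sel], norm_state(X))
  Xte <- expr_matrix(unclass(X)[, -sel], norm_state(X))
  Str <- surv_table(as.data.frame(co$survival)[sel, ])
  Ste <- right_censor(surv_table(as.data.frame(co$survival)[-sel, ]), 60)
  res <- suppressWarnings(
    random_signature_null(Xtr, Str, Xte, Ste, reference_p = 0,
                          sig = canon$signature, cfg = cost_config(),
                          k_sets = 20, n_restarts = 4, seed = 3))
  # a reference beating every panel sits at percentile 0
  expect_equal(res$percentile, 0)
  expect_length(res$panel_p, 20)
  expect_true(all(res$panel_p > 0 & res$panel_p <= 1))
  # a reference worse than or equal to every panel sits at percentile 1
  res1 <- suppressWarnings(
    random_signature_null(Xtr, Str, Xte, Ste, reference_p = 1,
                          sig = canon$signature, cfg = cost_config(),
                          k_sets = 20, n_restarts = 4, seed = 3))
  expect_equal(res1$percentile, 1)
  # identical seed, identical draw
  expect_equal(res$panel_p, res1$panel_p)

  expect_error(random_signature_null(Xtr, Str, Xte, Ste, 0.5,
                                     canon$signature, cost_config(),
                                     k_sets = 10),
               "k_sets")
})
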