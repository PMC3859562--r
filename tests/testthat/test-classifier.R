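canon <- canonical_bpms()

test_that("component activation uses strict inequalities in the right direction", {
  expect_identical(component_activation(0.50, 0.19, +1), 1L)
  expect_identical(component_activation(-0.50, -0.27, -1), 1L)
  expect_identical(component_activation(0.19, 0.19, +1), 0L)
  expect_identical(component_activation(-0.27, -0.27, -1), 0L)
  expect_identical(component_activation(c(-1, 0, 1), 0, +1), c(0L, 0L, 1L))
})

test_that("pathway scores count active components and saturate at 7", {
  sig <- canon$signature
  tau <- canon$thresholds
  # fully activated: RKIP far below, everything else far above
  full <- c(-2, 2, 2, 2, 2, 2, 2)
  expect_identical(pathway_score(full, tau, sig), 7L)
  # one component pulled back to inactive -> 6
  one_off <- full
  one_off[4] <- tau[["HMGA2"]]          # exact equality is inactive
  expect_identical(pathway_score(one_off, tau, sig), 6L)
  # everything inactive -> 0
  none <- c(2, -2, -2, -2, -2, -2, -2)
  expect_identical(pathway_score(none, tau, sig), 0L)
  expect_error(pathway_score(c(1, 2), tau, sig), "7")
})

test_that("classify matches a per-sample brute-force oracle and the label law", {
  sig <- canon$signature
  set.seed(123)
  for (rep in 1:4) {
    features <- matrix(rnorm(7 * 200, sd = 1.5), nrow = 7,
                       dimnames = list(sig$name, paste0("s", 1:200)))
    tau <- rnorm(7)
    got <- classify(features, tau, sig)
    oracle <- naive_classify(features, tau, sig$direction)
    expect_identical(got$score, oracle$score)
    expect_identical(got$label, oracle$label)
    expect_true(all(got$score >= 0 & got$score <= 7))
    expect_identical(got$label, as.integer(got$score == 7L))
  }

  # two samples, one fully activated
  f2 <- cbind(a = c(-2, 2, 2, 2, 2, 2, 2), b = c(-2, 2, 2, 2, 2, 2, -2))
  rownames(f2) <- sig$name
  expect_identical(classify(f2, canon$thresholds, sig)$label, c(1L, 0L))
})

test_that("raising an above-threshold component's cutoff never grows the cohort", {
  sig <- canon$signature
  set.seed(5)
  features <- matrix(rnorm(7 * 300), nrow = 7,
                     dimnames = list(sig$name, paste0("s", 1:300)))
  tau <- rep(0, 7)
  base <- sum(classify(features, tau, sig)$label)
  for (i in which(sig$direction == 1)) {
    up <- tau; up[i] <- up[i] + 0.5
    expect_lte(sum(classify(features, up, sig)$label), base)
  }
  # RKIP is below-threshold-active: raising its cutoff can only admit more
  dn <- tau; dn[1] <- dn[1] + 0.5
  expect_gte(sum(classify(features, dn, sig)$label), base)
})

test_that("feature assembly follows canonical order and names missing genes", {
  co <- generate_cohort(synthetic_config(n_samples = 30, seed = 2))
  F <- assemble_feature_matrix(co$expression, canon$signature, canon$metagenes)
  expect_identical(rownames(F), canon$signature$name)
  expect_equal(F["meta_let7_TG", ],
               build_metagene(co$expression, canon$metagenes$meta_let7_TG))
  expect_equal(F["meta_BACH1", ],
               build_metagene(co$expression, canon$metagenes$meta_BACH1))

  X_missing <- expr_matrix(unclass(co$expression)[rownames(co$expression) != "HMGA2", ],
                           norm_state(co$expression))
  expect_error(assemble_feature_matrix(X_missing, canon$signature,
                                       canon$metagenes), "HMGA2")
})

test_that("classification is invariant under sample permutation", {
  co <- generate_cohort(synthetic_config(n_samples = 50, seed = 9))
  F <- assemble_feature_matrix(co$expression, canon$signature, canon$metagenes)
  lab <- classify(F, canon$thresholds, canon$signature)
  perm <- sample(ncol(F))
  lab_p <- classify(F[, perm], canon$thresholds, canon$signature)
  expect_identical(lab_p$label[match(lab$sample_id, lab_p$sample_id)],
                   lab$label)
})

test_that("frozen references are deterministic and reject degenerate rows", {
  co <- generate_cohort(synthetic_config(n_samples = 100, seed = 3))
  ref1 <- freeze_reference(co$expression, canon$signature, canon$metagenes)
  ref2 <- freeze_reference(co$expression, canon$signature, canon$metagenes)
  expect_equal(as.data.frame(ref1), as.data.frame(ref2))
  expect_true(all(ref1$scale > 0))
  expect_setequal(ref1$gene,
                  signature_genes(canon$signature, canon$metagenes))

  flat <- unclass(co$expression)
  flat["OPN", ] <- 1.25
  expect_error(freeze_reference(expr_matrix(flat, "median_centered"),
                                canon$signature, canon$metagenes), "OPN")
  small <- expr_matrix(unclass(co$expression)[, 1:10], "median_centered")
  expect_error(freeze_reference(small, canon$signature, canon$metagenes),
               "20")
})

test_that("single-sample prediction is batch-independent and matches batch labels", {
  co <- generate_cohort(synthetic_config(n_samples = 100, seed = 3))
  ref <- freeze_reference(co$expression, canon$signature, canon$metagenes)

  # a sample sitting exactly at the reference location yields all-zero
  # standardized features (reference built with exactly-zero locations)
  genes <- signature_genes(canon$signature, canon$metagenes)
  sym <- t(vapply(seq_along(genes),
                  function(i) (0.5 + i / 10) * seq(-1, 1, length.out = 24),
                  numeric(24)))
  dimnames(sym) <- list(genes, paste0("r", 1:24))
  ref0 <- freeze_reference(expr_matrix(sym, "median_centered"),
                           canon$signature, canon$metagenes)
  expect_equal(ref0$location, rep(0, length(genes)))
  res0 <- classify_single_sample(setNames(rep(0, length(genes)), genes),
                                 ref0, canon$thresholds, canon$signature,
                                 canon$metagenes)
  zero_score <- pathway_score(rep(0, 7), canon$thresholds, canon$signature)
  expect_identical(res0$score, as.integer(zero_score))

  # SSP labels agree with batch-mode labels when the reference is the
  # cohort itself
  Xz <- zscore_genes(co$expression)
  feats <- assemble_feature_matrix(Xz, canon$signature, canon$metagenes)
  batch <- classify(feats, canon$thresholds, canon$signature)
  agree <- vapply(seq_len(ncol(co$expression)), function(i) {
    v <- setNames(unclass(co$expression)[, i], rownames(co$expression))
    ssp <- classify_single_sample(v, ref, canon$thresholds,
                                  canon$signature, canon$metagenes)
    ssp$label == batch$label[i]
  }, logical(1))
  expect_gte(mean(agree), 0.95)

  # missing singleton gene errors; partial meta-gene panel is tolerated
  v <- setNames(unclass(co$expression)[, 1], rownames(co$expression))
  expect_error(classify_single_sample(v[names(v) != "MMP1"], ref,
                                      canon$thresholds, canon$signature,
                                      canon$metagenes), "MMP1")
  v_part <- v[names(v) != "ARID3B"]
  expect_message(
    res_part <- classify_single_sample(v_part, ref, canon$thresholds,
                                       canon$signature, canon$metagenes,
                                       partial_panel = TRUE),
    "renormalized")
  expect_true(res_part$score %in% 0:7)
})

test_that("signature bundles survive a JSON round-trip", {
  path <- tempfile(fileext = ".json")
  write_signature_bundle(canon, path)
  back <- read_signature_bundle(path)
  expect_equal(back$thresholds, canon$thresholds)
  expect_equal(as.data.frame(back$signature), as.data.frame(canon$signature))
  expect_equal(back$metagenes$meta_BACH1$members,
               canon$metagenes$meta_BACH1$members)
})
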