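# Shared fixtures, built in code at test time.

# small genes x samples matrix with named dimensions
tiny_matrix <- function(values, genes, samples,
                        state = "raw_summarized") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  expr_matrix(m, state)
}

# write a genes-in-rows TSV and return its path
write_tsv_matrix <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# survival table from parallel vectors
mk_surv <- function(time, event, ids = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_along(time))
  surv_table(tibble::tibble(sample_id = ids, time_months = time,
                            event = as.integer(event)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent per-sample loop classifier (no vectorization), used as the
# oracle against classify()
naive_classify <- function(features, tau, directions) {
  n <- ncol(features)
  score <- integer(n)
  for (j in seq_len(n)) {
    s <- 0L
    for (i in seq_len(nrow(features))) {
      x <- features[i, j]
      active <- if (directions[i] > 0) x > tau[i] else x < tau[i]
      if (active) s <- s + 1L
    }
    score[j] <- s
  }
  list(score = score, label = as.integer(score == nrow(features)))
}

# simulate a simple exponential survival cohort with a binary covariate
sim_surv_cohort <- function(n, hr, base_rate = 0.01, horizon = 60,
                            p_pos = 0.3) {
  x <- as.integer(runif(n) < p_pos)
  t_ev <- rexp(n, rate = base_rate * hr^x)
  time <- pmin(t_ev, horizon)
  event <- as.integer(t_ev <= horizon)
  list(S = mk_surv(time, event), x = x)
}
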