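#' Meta-gene specification
#'
#' A meta-gene summarizes the activity of an upstream regulator (here the
#' microRNA let-7 or the transcription factor BACH1) as a weighted average
#' of its target genes' expression. Weights default to uniform — the
#' arithmetic mean of member rows — and must be non-negative and sum to 1.
#'
#' @param name meta-gene name.
#' @param members character vector of unique member gene symbols.
#' @param weights optional non-negative weights, same length as `members`,
#'   summing to 1; default uniform.
#' @return A `metagene_spec` object.
#' @export
metagene_spec <- function(name, members, weights = NULL) {
  members <- as.character(members)
  if (length(members) == 0L || anyDuplicated(toupper(members))) {
    abort("`members` must be a non-empty vector of unique gene symbols.")
  }
  if (is.null(weights)) {
    weights <- rep(1 / length(members), length(members))
  }
  if (length(weights) != length(members)) {
    abort("`weights` must match `members` in length.")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must be non-negative and sum to 1.")
  }
  structure(list(name = name, members = members, weights = weights),
            class = "metagene_spec")
}

#' @export
print.metagene_spec <- function(x, ...) {
  cat(sprintf("<metagene_spec> %s: %d members\n", x$name, length(x$members)))
  invisible(x)
}

# Case-insensitive lookup of gene symbols in the matrix rownames.
# Returns a list of integer row-index vectors (possibly length > 1 when
# several rows collapse to one symbol, in which case rows are averaged).
match_gene_rows <- function(X, symbols) {
  rn <- toupper(trimws(rownames(X)))
  lapply(toupper(trimws(symbols)), function(s) which(rn == s))
}

# Extract a per-sample expression vector for one symbol; rows mapping to
# the same symbol are averaged.
gene_values <- function(X, symbol) {
  idx <- match_gene_rows(X, symbol)[[1]]
  if (length(idx) == 0L) return(NULL)
  if (length(idx) > 1L) {
    inform(sprintf("%d rows map to '%s'; averaging.", length(idx), symbol))
    return(colMeans(unclass(X)[idx, , drop = FALSE]))
  }
  unclass(X)[idx, ]
}

#' Select the lowest-variance candidate genes
#'
#' Variance filtering is how the signature's target lists were slimmed:
#' among the candidate targets, keep the `k` genes with the smallest
#' across-sample variance (n - 1 denominator) on the training matrix.
#' Candidates missing from the matrix are dropped with a warning. Ties at
#' the cut are broken lexicographically by gene symbol.
#'
#' @param X an [expr_matrix()] (training cohort).
#' @param candidates character vector of candidate gene symbols.
#' @param k number of genes to keep.
#' @return Character vector of `k` gene symbols, ordered by increasing
#'   variance then symbol.
#' @export
variance_filter <- function(X, candidates, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) abort("`k` must be >= 1.")
  hits <- match_gene_rows(X, candidates)
  present <- lengths(hits) > 0L
  if (!any(present)) abort("No candidate gene is present in the matrix.")
  if (any(!present)) {
    warn(paste0("Dropping candidates absent from matrix: ",
                paste(candidates[!present], collapse = ", ")))
  }
  cand <- candidates[present]
  if (length(cand) < k) {
    abort(sprintf("Only %d candidate(s) present; cannot keep k = %d.",
                  length(cand), k))
  }
  vars <- vapply(cand, function(s) var(gene_values(X, s)), numeric(1))
  ord <- order(vars, cand)
  cand[ord][seq_len(k)]
}

#' Build a meta-gene from an expression matrix
#'
#' Computes the per-sample weighted average of the member genes' rows.
#' Members absent from the matrix are dropped and the remaining weights
#' renormalized (reported via a message), so partial gene panels degrade
#' gracefully rather than failing.
#'
#' @param X an [expr_matrix()].
#' @param spec a [metagene_spec()].
#' @return Named numeric vector (one value per sample).
#' @export
build_metagene <- function(X, spec) {
  stopifnot(inherits(spec, "metagene_spec"))
  hits <- match_gene_rows(X, spec$members)
  present <- lengths(hits) > 0L
  if (!any(present)) {
    abort(sprintf("No member of meta-gene '%s' is present in the matrix.",
                  spec$name))
  }
  if (any(!present)) {
    inform(sprintf("Meta-gene '%s': dropping %d absent member(s) (%s); weights renormalized.",
                   spec$name, sum(!present),
                   paste(spec$members[!present], collapse = ", ")))
  }
  w <- spec$weights[present]
  w <- w / sum(w)
  rows <- vapply(spec$members[present], function(s) gene_values(X, s),
                 numeric(ncol(X)))
  if (!is.matrix(rows)) rows <- matrix(rows, nrow = 1L)
  # vapply returns samples x members; weighted row sums give the meta-gene
  out <- as.numeric(rows %*% w)
  names(out) <- colnames(X)
  out
}

#' Normal Q-Q diagnostic for a meta-gene
#'
#' Pairs the sorted empirical values with standard-normal quantiles
#' (Blom-style plotting positions via [stats::ppoints()]) and reports
#' their Pearson correlation. Meta-gene values are expected to be close to
#' normal — averages of many roughly-normal member genes — so the
#' correlation should sit near 1; heavy-tailed departures pull it down.
#'
#' @param values numeric vector, at least 10 finite non-constant values.
#' @return A `qq_diag` object: tibble of `(theoretical, empirical)`
#'   quantile pairs plus a `correlation` attribute.
#' @export
qq_normal_diagnostic <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 10L) abort("Need at least 10 finite values.")
  if (sd(values) == 0) abort("Values are constant; Q-Q diagnostic undefined.")
  emp <- sort(values)
  theo <- qnorm(ppoints(length(emp)))
  out <- tibble(theoretical = theo, empirical = emp)
  structure(out, correlation = cor(theo, emp),
            class = c("qq_diag", class(tibble())))
}

#' @export
print.qq_diag <- function(x, ...) {
  cat(sprintf("<qq_diag> n = %d, quantile correlation = %.4f\n",
              nrow(x), attr(x, "correlation")))
  NextMethod()
}

#' @rdname qq_normal_diagnostic
#' @param object a `qq_diag` object.
#' @param ... unused.
#' @method autoplot qq_diag
#' @export
autoplot.qq_diag <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$theoretical, y = .data$empirical)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_abline(slope = sd(object$empirical), intercept = mean(object$empirical),
                colour = "red") +
    labs(x = "Standard normal quantiles", y = "Empirical quantiles",
         title = sprintf("Normal Q-Q (r = %.4f)", attr(object, "correlation"))) +
    theme_minimal()
}
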