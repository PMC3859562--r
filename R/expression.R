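#' Expression matrix container
#'
#' An `expr_matrix` is a genes x samples numeric matrix carrying a
#' `normalization_state` attribute that records where the data sits in the
#' preprocessing chain: `"raw_summarized"` (probe-summarized log-scale
#' values), `"median_centered"` (per-sample median subtracted) or
#' `"zscored"` (per-gene standardized). Gene ids are rownames, sample ids
#' colnames; both must be unique and all values finite.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene symbols) and colnames (sample ids).
#' @param normalization_state one of `"raw_summarized"`,
#'   `"median_centered"`, `"zscored"`.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values,
                        normalization_state = c("raw_summarized",
                                                "median_centered",
                                                "zscored")) {
  normalization_state <- match.arg(normalization_state)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have rownames (gene ids) and colnames (sample ids).")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    abort(paste0("Duplicate gene id: '", dup, "'."))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    abort(paste0("Duplicate sample id: '", dup, "'."))
  }
  if (!all(is.finite(values))) {
    abort("Expression values must all be finite.")
  }
  structure(values,
            normalization_state = normalization_state,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), norm_state(x)))
  k <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(m), drop = FALSE])
  if (nrow(x) > k || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' Normalization state of an expression matrix
#' @param x an `expr_matrix`.
#' @return A string: the current normalization state.
#' @export
norm_state <- function(x) {
  attr(x, "normalization_state") %||% "raw_summarized"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a delimited expression matrix
#'
#' Reads a tab- or comma-separated text matrix of expression values. By
#' default genes are rows (first column gene ids, header row sample ids);
#' `orientation = "samples_in_rows"` reads the transposed layout.
#' Delimiter is sniffed from the header line (tab wins over comma).
#'
#' @param path path to a TSV/CSV file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return An [expr_matrix()] with `normalization_state = "raw_summarized"`,
#'   row/column order as in the file.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows",
                                                   "samples_in_rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort(paste0("Empty or header-only file: ", path))
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  header <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  col_ids <- trimws(header[-1])
  body <- strsplit(lines[-1], sep, fixed = TRUE)
  row_ids <- trimws(vapply(body, `[`, character(1), 1L))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(col_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1]
    if (length(cells) != length(col_ids)) {
      abort(sprintf("Row %d ('%s') has %d values; expected %d.",
                    i, row_ids[i], length(cells), length(col_ids)))
    }
    v <- suppressWarnings(as.numeric(cells))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      abort(sprintf("Non-numeric cell '%s' at row %d ('%s'), column %d ('%s').",
                    cells[j], i, row_ids[i], j, col_ids[j]))
    }
    vals[i, ] <- v
  }
  rownames(vals) <- row_ids
  colnames(vals) <- col_ids
  if (orientation == "samples_in_rows") vals <- t(vals)
  expr_matrix(vals, "raw_summarized")
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: genes as rows, first column
#' `gene_id`, header row of sample ids.
#'
#' @param X an [expr_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(X, path) {
  df <- data.frame(gene_id = rownames(X), unclass(X),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median-center each sample
#'
#' Subtracts the per-sample (column) median so that every sample's median
#' expression is zero — the first step of the preprocessing chain applied
#' to each cohort before threshold training. Constant columns become
#' all-zero.
#'
#' @param X an [expr_matrix()].
#' @return An [expr_matrix()] with state `"median_centered"`.
#' @export
median_center_samples <- function(X) {
  meds <- apply(unclass(X), 2L, median)
  out <- sweep(unclass(X), 2L, meds, `-`)
  expr_matrix(out, "median_centered")
}

#' Z-score each gene across samples
#'
#' Standardizes each gene row to mean 0 and unit sample standard deviation
#' (n - 1 denominator). Constant rows map to all-zero with a warning;
#' downstream variance filtering removes such genes anyway.
#'
#' @param X an [expr_matrix()] with at least 2 samples.
#' @return An [expr_matrix()] with state `"zscored"`.
#' @export
zscore_genes <- function(X) {
  if (ncol(X) < 2L) abort("z-scoring needs at least 2 samples.")
  v <- unclass(X)
  mu <- rowMeans(v)
  s <- apply(v, 1L, sd)
  flat <- s <= 0
  if (any(flat)) {
    warn(sprintf("%d constant gene row(s) z-scored to zero (e.g. '%s').",
                 sum(flat), rownames(v)[which(flat)[1]]))
    s[flat] <- 1
    mu[flat] <- v[flat, 1L]
  }
  out <- (v - mu) / s
  expr_matrix(out, "zscored")
}

#' Read a survival table
#'
#' Reads a TSV/CSV with columns `sample_id`, `time_months`, `event`
#' (1 = distant metastasis observed, 0 = censored).
#'
#' @param path path to the file.
#' @return A `surv_table` tibble with columns `sample_id`, `time_months`,
#'   `event`, plus a `censor_horizon` attribute (NULL until
#'   [right_censor()] is applied).
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, sep = "", header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 1L) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "time_months", "event")
  if (!all(need %in% names(df))) {
    abort(paste0("Survival table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  surv_table(tibble(sample_id = as.character(df$sample_id),
                    time_months = as.numeric(df$time_months),
                    event = as.integer(df$event)))
}

#' Construct and validate a survival table
#'
#' @param df data frame with columns `sample_id`, `time_months`, `event`.
#' @param censor_horizon censoring horizon in months, or NULL.
#' @return A validated `surv_table` tibble.
#' @export
surv_table <- function(df, censor_horizon = NULL) {
  df <- as_tibble(df)
  if (anyDuplicated(df$sample_id)) {
    dup <- df$sample_id[duplicated(df$sample_id)][1]
    abort(paste0("Duplicate sample id in survival table: '", dup, "'."))
  }
  if (any(!is.finite(df$time_months)) || any(df$time_months < 0)) {
    abort("Survival times must be finite and non-negative.")
  }
  if (!all(df$event %in% c(0L, 1L))) {
    abort("`event` must be 0 or 1.")
  }
  df$event <- as.integer(df$event)
  structure(df, censor_horizon = censor_horizon,
            class = c("surv_table", class(tibble())))
}

#' Write a survival table to TSV
#' @param S a `surv_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(S, path) {
  utils::write.table(as.data.frame(S)[, c("sample_id", "time_months", "event")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Right-censor survival data at a horizon
#'
#' Caps follow-up at `horizon` months: times beyond the horizon are set to
#' the horizon and their events recoded to censored. Five-year (60-month)
#' censoring is the convention used for every validation cohort; training
#' halves are left uncensored.
#'
#' @param S a `surv_table`.
#' @param horizon positive horizon in months (years * 12 if converting).
#' @return A `surv_table` with `censor_horizon` recorded.
#' @export
right_censor <- function(S, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    abort("`horizon` must be a single positive number of months.")
  }
  over <- S$time_months > horizon
  S$event[over] <- 0L
  S$time_months[over] <- horizon
  surv_table(S, censor_horizon = horizon)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. The packaged fixture `bpms_targets.gmt` carries the
#' 12-gene let-7 target list and the 13-gene BACH1 target list used by the
#' two signature meta-genes.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors (set members).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) {
      abort(sprintf("Empty GMT line %d in %s.", i, path))
    }
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (length(fields) < 3L) {
      abort(sprintf("GMT line %d has %d field(s); need name, description and at least one member.",
                    i, length(fields)))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      abort(sprintf("GMT line %d ('%s') has no members.", i, fields[1]))
    }
    sets[[fields[1]]] <- members
  }
  sets
}

#' Path to the packaged let-7 / BACH1 target gene sets
#' @return File path of the installed GMT fixture.
#' @export
bpms_targets_path <- function() {
  system.file("extdata", "bpms_targets.gmt", package = "bpmsig",
              mustWork = TRUE)
}
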