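#' Signature definition
#'
#' The BPMS is an ordered list of seven components, each either a single
#' gene or a meta-gene, with an activation direction: `+1` components are
#' active when expression is strictly above their threshold, `-1`
#' components when strictly below. The canonical order is RKIP (-1),
#' meta-let-7-TG (+1), meta-BACH1 (+1), HMGA2 (+1), MMP1 (+1), CXCR4 (+1),
#' OPN (+1): the pathway is driven by RKIP *suppression*, so RKIP is the
#' one below-threshold-active component.
#'
#' @param components tibble/data frame with columns `name`, `kind`
#'   (`"gene"` or `"metagene"`) and `direction` (+1 or -1).
#' @return A `signature_def` tibble.
#' @export
signature_def <- function(components) {
  components <- as_tibble(components)
  need <- c("name", "kind", "direction")
  if (!all(need %in% names(components))) {
    abort("`components` needs columns name, kind, direction.")
  }
  if (anyDuplicated(components$name)) {
    abort("Component names must be unique.")
  }
  if (!all(components$kind %in% c("gene", "metagene"))) {
    abort("`kind` must be 'gene' or 'metagene'.")
  }
  if (!all(components$direction %in% c(-1, 1))) {
    abort("`direction` must be +1 or -1.")
  }
  structure(components, class = c("signature_def", class(tibble())))
}

#' Validate a threshold vector against a signature
#' @param tau numeric thresholds (z-score units), one per component; names
#'   optional but, if present, must match the component names.
#' @param sig a [signature_def()].
#' @return Named numeric vector ordered as the signature.
#' @export
threshold_vector <- function(tau, sig) {
  if (length(tau) != nrow(sig)) {
    abort(sprintf("Need %d thresholds, got %d.", nrow(sig), length(tau)))
  }
  if (!all(is.finite(tau))) abort("Thresholds must be finite.")
  if (!is.null(names(tau))) {
    if (!setequal(names(tau), sig$name)) {
      abort("Threshold names do not match signature component names.")
    }
    tau <- tau[sig$name]
  } else {
    names(tau) <- sig$name
  }
  tau
}

#' The published BPMS signature bundle
#'
#' Returns the packaged signature exactly as published: the seven ordered
#' components, the averaged trained thresholds (-0.27 RKIP, -0.020
#' meta-let-7-TG, -0.15 meta-BACH1, -0.20 HMGA2, -0.23 MMP1, -0.19 CXCR4,
#' 0.19 OPN, in z-score units on sample-median-centered, gene-z-scored
#' data) and the two meta-gene member lists (12 let-7 targets, 13 BACH1
#' targets), for 30 distinct genes in total.
#'
#' @return A list with elements `signature` ([signature_def()]),
#'   `thresholds` (named numeric) and `metagenes` (named list of
#'   [metagene_spec()]).
#' @export
canonical_bpms <- function() {
  sig <- signature_def(tibble(
    name = c("RKIP", "meta_let7_TG", "meta_BACH1",
             "HMGA2", "MMP1", "CXCR4", "OPN"),
    kind = c("gene", "metagene", "metagene", "gene", "gene", "gene", "gene"),
    direction = c(-1, 1, 1, 1, 1, 1, 1)
  ))
  tau <- threshold_vector(
    c(RKIP = -0.27, meta_let7_TG = -0.020, meta_BACH1 = -0.15,
      HMGA2 = -0.20, MMP1 = -0.23, CXCR4 = -0.19, OPN = 0.19),
    sig)
  sets <- read_gene_sets(bpms_targets_path())
  specs <- list(
    meta_let7_TG = metagene_spec("meta_let7_TG", sets$let7_targets),
    meta_BACH1   = metagene_spec("meta_BACH1", sets$bach1_targets)
  )
  list(signature = sig, thresholds = tau, metagenes = specs)
}

#' All gene symbols a signature requires
#' @param sig a [signature_def()].
#' @param specs named list of [metagene_spec()] for metagene components.
#' @return Character vector of distinct gene symbols.
#' @export
signature_genes <- function(sig, specs) {
  genes <- sig$name[sig$kind == "gene"]
  for (nm in sig$name[sig$kind == "metagene"]) {
    genes <- c(genes, specs[[nm]]$members)
  }
  unique(genes)
}

#' Assemble the component feature matrix
#'
#' Builds the 7 x n matrix the classifier consumes: one row per signature
#' component in canonical order — single genes copied from the expression
#' matrix (rows collapsing to one symbol are averaged), meta-gene rows
#' computed with [build_metagene()].
#'
#' @param X an [expr_matrix()] (normally median-centered and z-scored).
#' @param sig a [signature_def()].
#' @param specs named list of [metagene_spec()], one per metagene
#'   component.
#' @return Numeric matrix, `nrow(sig)` x `ncol(X)`, rownames = component
#'   names, colnames = sample ids.
#' @export
assemble_feature_matrix <- function(X, sig, specs) {
  out <- matrix(NA_real_, nrow = nrow(sig), ncol = ncol(X),
                dimnames = list(sig$name, colnames(X)))
  for (i in seq_len(nrow(sig))) {
    nm <- sig$name[i]
    if (sig$kind[i] == "gene") {
      v <- gene_values(X, nm)
      if (is.null(v)) abort(paste0("Gene component '", nm,
                                   "' is missing from the matrix."))
      out[i, ] <- v
    } else {
      if (is.null(specs[[nm]])) {
        abort(paste0("No metagene_spec supplied for component '", nm, "'."))
      }
      out[i, ] <- build_metagene(X, specs[[nm]])
    }
  }
  out
}

#' Component activation indicator
#'
#' A component is active when its expression lies strictly past its
#' threshold in the activation direction: `x > tau` for direction +1,
#' `x < tau` for direction -1. Exact equality counts as inactive.
#'
#' @param x expression value(s).
#' @param tau threshold.
#' @param direction +1 or -1.
#' @return Integer 0/1, vectorized over `x`.
#' @export
component_activation <- function(x, tau, direction) {
  if (!all(is.finite(x)) || !is.finite(tau)) abort("Inputs must be finite.")
  if (!direction %in% c(-1, 1)) abort("`direction` must be +1 or -1.")
  as.integer(if (direction > 0) x > tau else x < tau)
}

# 0/1 activation matrix (components x samples), vectorized over samples
activation_matrix <- function(features, tau, sig) {
  d <- sig$direction
  up <- features > tau        # tau recycles down rows (components)
  dn <- features < tau
  act <- up
  act[d < 0, ] <- dn[d < 0, , drop = FALSE]
  storage.mode(act) <- "integer"
  act
}

#' Pathway-activation score of one sample
#'
#' Counts how many of the seven components are active; 7 means the entire
#' RKIP-suppression/BACH1-activation cascade is engaged.
#'
#' @param features numeric 7-vector, component order as in `sig`.
#' @param tau a [threshold_vector()].
#' @param sig a [signature_def()].
#' @return Integer in 0..7.
#' @export
pathway_score <- function(features, tau, sig) {
  if (length(features) != nrow(sig)) {
    abort(sprintf("Need %d features, got %d.", nrow(sig), length(features)))
  }
  tau <- threshold_vector(tau, sig)
  sum(vapply(seq_len(nrow(sig)), function(i) {
    component_activation(features[i], tau[i], sig$direction[i])
  }, integer(1)))
}

#' Classify a cohort with the threshold signature
#'
#' Applies the binary classifier to every sample: score = number of active
#' components, label = 1 (BPMS-positive, high metastatic risk) iff the
#' score is exactly 7.
#'
#' @param features components x samples numeric matrix (see
#'   [assemble_feature_matrix()]).
#' @param tau a [threshold_vector()].
#' @param sig a [signature_def()].
#' @return A tibble with columns `sample_id`, `score`, `label`.
#' @export
classify <- function(features, tau, sig) {
  if (!is.matrix(features) || ncol(features) < 1L) {
    abort("`features` must be a non-empty components x samples matrix.")
  }
  if (nrow(features) != nrow(sig)) {
    abort(sprintf("Feature matrix has %d rows; signature has %d components.",
                  nrow(features), nrow(sig)))
  }
  tau <- threshold_vector(tau, sig)
  score <- colSums(activation_matrix(features, tau, sig))
  tibble(sample_id = colnames(features) %||% as.character(seq_len(ncol(features))),
         score = as.integer(score),
         label = as.integer(score == nrow(sig)))
}

#' Freeze single-sample normalization parameters from a reference cohort
#'
#' The single-sample predictor (SSP) mode replaces cohort-dependent
#' z-scoring with a frozen set of per-gene location/scale parameters
#' estimated once on a reference cohort, so that a sample's label never
#' depends on whatever other samples are processed alongside it. The
#' reference matrix is median-centered by sample first (a per-sample
#' operation, itself batch-independent); the stored parameters are each
#' required gene's mean and n-1 standard deviation on the centered
#' reference.
#'
#' @param X_ref reference [expr_matrix()] with >= 20 samples
#'   (`raw_summarized` or `median_centered`; raw input is centered first).
#' @param sig a [signature_def()].
#' @param specs named list of [metagene_spec()].
#' @return A `frozen_reference`: tibble (`gene`, `location`, `scale`) plus
#'   provenance attributes.
#' @export
freeze_reference <- function(X_ref, sig, specs) {
  if (ncol(X_ref) < 20L) abort("Reference cohort must have >= 20 samples.")
  if (norm_state(X_ref) == "raw_summarized") {
    X_ref <- median_center_samples(X_ref)
  }
  genes <- signature_genes(sig, specs)
  rows <- lapply(genes, function(g) gene_values(X_ref, g))
  present <- !vapply(rows, is.null, logical(1))
  if (any(!present)) {
    abort(paste0("Reference matrix is missing required gene(s): ",
                 paste(genes[!present], collapse = ", ")))
  }
  loc <- vapply(rows, mean, numeric(1))
  sca <- vapply(rows, sd, numeric(1))
  if (any(sca <= 0)) {
    abort(paste0("Constant reference row(s): ",
                 paste(genes[sca <= 0], collapse = ", "),
                 "; cannot freeze a zero scale."))
  }
  structure(tibble(gene = genes, location = loc, scale = sca),
            n_reference_samples = ncol(X_ref),
            class = c("frozen_reference", class(tibble())))
}

#' Classify one sample with frozen-reference normalization
#'
#' Standardizes a single raw sample against a [freeze_reference()] bundle
#' and classifies it. The sample is median-centered against its own gene
#' median, each required gene is standardized with the frozen per-gene
#' location/scale, the seven features are assembled and scored. The result
#' is identical whether the sample is processed alone or in any batch.
#'
#' @param raw_sample named numeric vector of per-gene raw (log-scale)
#'   expression values, covering the signature genes (ideally the full
#'   array, so the sample median is well estimated).
#' @param ref a `frozen_reference`.
#' @param tau a [threshold_vector()].
#' @param sig a [signature_def()].
#' @param specs named list of [metagene_spec()].
#' @param partial_panel if TRUE, missing meta-gene members are tolerated
#'   (weights renormalized, reported); missing singleton genes always
#'   error.
#' @return A one-row tibble with `score` and `label`.
#' @export
classify_single_sample <- function(raw_sample, ref, tau, sig, specs,
                                   partial_panel = FALSE) {
  if (is.null(names(raw_sample))) abort("`raw_sample` must be named by gene.")
  centered <- raw_sample - median(raw_sample)
  names(centered) <- toupper(trimws(names(raw_sample)))
  lookup <- setNames(seq_len(nrow(ref)), toupper(trimws(ref$gene)))
  std <- function(gene) {
    g <- toupper(trimws(gene))
    i <- lookup[[g]]
    if (is.null(i)) abort(paste0("Gene '", gene, "' absent from frozen reference."))
    if (!g %in% names(centered)) return(NULL)
    (centered[[g]] - ref$location[[i]]) / ref$scale[[i]]
  }
  tau <- threshold_vector(tau, sig)
  feats <- numeric(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    nm <- sig$name[i]
    if (sig$kind[i] == "gene") {
      v <- std(nm)
      if (is.null(v)) abort(paste0("Sample is missing required gene '", nm, "'."))
      feats[i] <- v
    } else {
      spec <- specs[[nm]]
      vals <- lapply(spec$members, std)
      present <- !vapply(vals, is.null, logical(1))
      if (!any(present)) {
        abort(paste0("Sample has no member of meta-gene '", nm, "'."))
      }
      if (any(!present) && !partial_panel) {
        abort(paste0("Sample is missing meta-gene member(s): ",
                     paste(spec$members[!present], collapse = ", "),
                     " (set partial_panel = TRUE to renormalize)."))
      }
      if (any(!present)) {
        inform(sprintf("Meta-gene '%s': %d member(s) missing; weights renormalized.",
                       nm, sum(!present)))
      }
      w <- spec$weights[present]
      feats[i] <- sum(unlist(vals[present]) * w / sum(w))
    }
  }
  score <- pathway_score(feats, tau, sig)
  tibble(score = as.integer(score),
         label = as.integer(score == nrow(sig)))
}

#' Write / read a signature bundle as JSON
#'
#' Serializes components, thresholds, meta-gene specs and (optionally) a
#' frozen reference into one JSON document, the exchange format between
#' training and application.
#'
#' @param bundle list with `signature`, `thresholds`, `metagenes`, and
#'   optionally `frozen_reference`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_bundle <- function(bundle, path) {
  obj <- list(
    components = as.data.frame(bundle$signature),
    thresholds = as.list(bundle$thresholds),
    metagenes = lapply(bundle$metagenes, function(s) {
      list(name = s$name, members = s$members, weights = s$weights)
    })
  )
  if (!is.null(bundle$frozen_reference)) {
    obj$frozen_reference <- as.data.frame(bundle$frozen_reference)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature_bundle
#' @export
read_signature_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sig <- signature_def(obj$components)
  tau <- threshold_vector(unlist(obj$thresholds), sig)
  specs <- lapply(obj$metagenes, function(s) {
    metagene_spec(s$name, s$members, s$weights)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  out <- list(signature = sig, thresholds = tau, metagenes = specs)
  if (!is.null(obj$frozen_reference)) {
    out$frozen_reference <- structure(
      as_tibble(obj$frozen_reference),
      class = c("frozen_reference", class(tibble())))
  }
  out
}
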