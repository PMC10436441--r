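#' Expression matrix of AFI protein signals
#'
#' Container for an analyte-by-sample grid of AFI (averaged fluorescence
#' intensity) values together with sample metadata and an explicit scale tag.
#' The tag records how far along the processing chain the values are and the
#' processing functions enforce the ordering
#' `raw_afi -> total_normalized -> log2 -> median_centered`
#' (imputation is permitted on the first two scales).
#'
#' @param values numeric matrix, analytes in rows, samples in columns; both
#'   dimnames must be set.
#' @param scale_tag one of `"raw_afi"`, `"total_normalized"`, `"log2"`,
#'   `"median_centered"`.
#' @param samples optional data.frame of per-sample metadata with a
#'   `sample_id` column matching `colnames(values)` (extra columns such as
#'   `tissue` (PDM/PTT), `subtype`, `histotype`, `pair_id` are carried along).
#' @param analytes optional data.frame of per-analyte metadata with an
#'   `analyte_id` column matching `rownames(values)` (e.g. a `pathway` column).
#' @param centering_scope character vector of sample ids used for median
#'   centering (recorded by [median_center_log2()]).
#' @param below_limit optional logical matrix of the same shape flagging cells
#'   imputed as weak signals.
#'
#' @return an object of class `expression_matrix`.
#' @seealso [build_afi_matrix()], [normalize_total_protein()],
#'   [impute_weak_signals()], [median_center_log2()]
#' @export
expression_matrix <- function(values, scale_tag = "raw_afi", samples = NULL,
                              analytes = NULL, centering_scope = NULL,
                              below_limit = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_named("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_named("'values' must have analyte rownames and sample colnames")
  }
  scale_tag <- match.arg(scale_tag, scale_tag_levels())
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(values),
                          stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(samples)) {
    stop_named("'samples' metadata needs a 'sample_id' column")
  }
  if (!setequal(samples$sample_id, colnames(values))) {
    stop_named("sample metadata does not match matrix columns")
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(analytes)) {
    analytes <- data.frame(analyte_id = rownames(values),
                           stringsAsFactors = FALSE)
  }
  if (!"analyte_id" %in% names(analytes) ||
      !setequal(analytes$analyte_id, rownames(values))) {
    stop_named("analyte metadata does not match matrix rows")
  }
  analytes <- analytes[match(rownames(values), analytes$analyte_id), ,
                       drop = FALSE]
  rownames(analytes) <- NULL
  if (!is.null(below_limit)) {
    stopifnot(is.logical(below_limit), all(dim(below_limit) == dim(values)))
  }
  structure(
    list(values = values, scale_tag = scale_tag, samples = samples,
         analytes = analytes, centering_scope = centering_scope,
         below_limit = below_limit),
    class = "expression_matrix"
  )
}

scale_tag_levels <- function() {
  c("raw_afi", "total_normalized", "log2", "median_centered")
}

# enforce the one-way scale ordering; `allowed` = tags a stage accepts
check_scale <- function(em, allowed, op) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!em$scale_tag %in% allowed) {
    stop_named(
      "%s expects a matrix on scale %s, got '%s' (scale transitions are one-way)",
      op, paste(sQuote(allowed), collapse = " or "), em$scale_tag)
  }
  invisible(em)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d analytes x %d samples [scale: %s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  if (!is.null(x$centering_scope)) {
    cat(sprintf("  centering scope: %d samples\n", length(x$centering_scope)))
  }
  if ("tissue" %in% names(x$samples)) {
    cat("  tissue:", paste(sprintf("%s=%d", names(table(x$samples$tissue)),
                                   table(x$samples$tissue)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
as.matrix.expression_matrix <- function(x, ...) x$values

#' Subset an expression matrix by sample ids
#'
#' @param em an [expression_matrix()].
#' @param sample_ids sample ids to keep (in this order).
#' @return an `expression_matrix` restricted to the requested samples.
#' @export
select_samples <- function(em, sample_ids) {
  stopifnot(inherits(em, "expression_matrix"))
  missing <- setdiff(sample_ids, colnames(em$values))
  if (length(missing)) {
    stop_named("unknown sample ids: %s", paste(missing, collapse = ", "))
  }
  expression_matrix(
    em$values[, sample_ids, drop = FALSE], em$scale_tag,
    samples = em$samples[match(sample_ids, em$samples$sample_id), ,
                         drop = FALSE],
    analytes = em$analytes, centering_scope = em$centering_scope,
    below_limit = if (!is.null(em$below_limit)) {
      em$below_limit[, sample_ids, drop = FALSE]
    }
  )
}
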