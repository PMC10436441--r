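# Validated CSV readers/writers and end-to-end orchestration.
# CSV is the single tabular interchange format: UTF-8, comma-delimited,
# '.' decimal, full-precision floats (so write -> read round trips exactly).

table_schemas <- function() {
  list(
    profiles = list(
      cols = c("sample_id", "antibody_id", "fraction_index", "mfi"),
      check = function(d) {
        v <- schema_check_numeric(d, "mfi", min = 0)
        v <- rbind(v, schema_check_numeric(d, "fraction_index", min = 0,
                                           max = 95))
        key <- paste(d$sample_id, d$antibody_id)
        cnt <- table(key)
        bad <- names(cnt)[cnt != 96]
        if (length(bad)) {
          v <- rbind(v, data.frame(
            row = NA_integer_, column = "fraction_index",
            message = sprintf("lane %s has %d fractions (expected 96 fractions)",
                              bad[1], cnt[bad[1]])))
        }
        v
      }),
    calibration = list(
      cols = c("fraction_index", "kda"),
      check = function(d) schema_check_numeric(d, "kda", min = 1e-12)),
    peak_specs = list(
      cols = c("analyte_id", "antibody_id", "expected_mw"),
      check = function(d) schema_check_numeric(d, "expected_mw", min = 1e-12)),
    totals = list(
      cols = c("sample_id", "total_protein"),
      check = function(d) schema_check_numeric(d, "total_protein",
                                               min = 1e-12)),
    cytotox = list(
      cols = c("sample_id", "drug", "timepoint_h", "replicate_id", "role",
               "rfu"),
      check = function(d) {
        v <- schema_check_numeric(d, "rfu", min = 0)
        bad <- which(!d$role %in% c("treatment", "vehicle", "blank"))
        if (length(bad)) {
          v <- rbind(v, data.frame(row = bad[1], column = "role",
                                   message = sprintf("unknown role '%s'",
                                                     d$role[bad[1]])))
        }
        v
      }),
    panel = list(
      cols = c("drug", "direction", "analyte_id"),
      check = function(d) {
        bad <- which(!d$direction %in% c("resistance", "sensitivity"))
        if (length(bad)) {
          data.frame(row = bad[1], column = "direction",
                     message = "direction must be resistance or sensitivity")
        } else {
          empty_violations()
        }
      }),
    pathway_map = list(
      cols = c("analyte_id", "pathway"),
      check = function(d) empty_violations())
  )
}

empty_violations <- function() {
  data.frame(row = integer(0), column = character(0), message = character(0))
}

schema_check_numeric <- function(d, col, min = -Inf, max = Inf) {
  x <- suppressWarnings(as.numeric(d[[col]]))
  bad <- which(is.na(x) | x < min | x > max)
  if (length(bad) == 0) return(empty_violations())
  data.frame(row = bad, column = col,
             message = sprintf("value %s out of range [%s, %s]",
                               as.character(d[[col]][bad]), format(min),
                               format(max)))
}

#' Validate a pipeline input file against its schema
#'
#' Row/column-level validation of the documented CSV dialects; never mutates
#' the input. Schemas: `profiles`, `calibration`, `peak_specs`, `totals`,
#' `cytotox`, `panel`, `pathway_map`.
#'
#' @param path CSV file path.
#' @param schema schema name (see above).
#' @return list with `ok` (logical) and `violations` (data.frame
#'   `row, column, message`).
#' @export
validate_inputs <- function(path, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) {
    stop_named("unknown schema '%s' (known: %s)", schema,
               paste(names(schemas), collapse = ", "))
  }
  if (!file.exists(path)) stop_named("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  sc <- schemas[[schema]]
  missing <- setdiff(sc$cols, names(d))
  if (length(missing)) {
    return(list(ok = FALSE, violations = data.frame(
      row = NA_integer_, column = missing,
      message = sprintf("missing required column '%s'", missing))))
  }
  v <- sc$check(d)
  list(ok = nrow(v) == 0, violations = v)
}

#' Write / read a pipeline table as CSV
#'
#' Full-precision CSV writers and readers for the pipeline's tables; numeric
#' values are serialized with `format(..., digits = 17)` so a write-read
#' round trip is bit-exact.
#'
#' @param d data.frame to write.
#' @param path file path.
#' @return `write_table_csv` returns `path` invisibly; `read_table_csv` the
#'   data.frame.
#' @export
write_table_csv <- function(d, path) {
  out <- d
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(x) {
        if (is.na(x)) "" else format(x, digits = 17, scientific = TRUE)
      }, character(1))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop_named("file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an expression matrix as CSV
#'
#' Analytes as rows, samples as columns; the scale tag (and centering scope)
#' is stored in `#`-prefixed header comments so the processing state
#' round-trips with the values.
#'
#' @param em an [expression_matrix()].
#' @param path file path.
#' @return `write_expression_matrix` returns `path` invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale_tag: %s", em$scale_tag), con)
  if (!is.null(em$centering_scope)) {
    writeLines(sprintf("# centering_scope: %s",
                       paste(em$centering_scope, collapse = ";")), con)
  }
  vals <- apply(em$values, c(1, 2), function(x) format(x, digits = 17))
  df <- data.frame(analyte_id = rownames(em$values), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @param samples optional sample metadata to attach on read.
#' @export
read_expression_matrix <- function(path, samples = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  tag <- sub("^# scale_tag: *", "", grep("^# scale_tag:", hdr, value = TRUE))
  if (length(tag) != 1) stop_named("no scale_tag header in %s", path)
  scope_line <- grep("^# centering_scope:", hdr, value = TRUE)
  scope <- if (length(scope_line)) {
    strsplit(sub("^# centering_scope: *", "", scope_line), ";")[[1]]
  } else NULL
  d <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                    collapse = "\n"),
                       stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d$analyte_id
  expression_matrix(m, tag, samples = samples, centering_scope = scope)
}

#' Run the full analysis pipeline on one configuration
#'
#' Executes the stages in dependency order — synthetic-data simulation (if
#' requested), bead-array signal processing to the centered expression
#' matrix, drug-responder calling, and the downstream profiling statistics —
#' writing every artifact plus a JSON run report (parameters, warnings,
#' outputs with MD5 content hashes) to `out_dir`. Identical configurations
#' produce identical artifacts.
#'
#' @param config named list (or path to a YAML file) with entries
#'   `seed`, `out_dir`, optional `cohort` (arguments to [cohort_config()]),
#'   `cytotox` (arguments to [simulate_cytotox_plate()]), and analysis
#'   parameters `alpha` (0.05), `z_cut` (3.5), `q_level` (0.05),
#'   `fc_threshold` (1), `center_scope` (`"all"`), `linkage`
#'   (`"complete"`). Unknown keys are rejected.
#' @return the run report, invisibly (list; also written as
#'   `run_report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "cohort", "cytotox", "alpha", "z_cut",
             "q_level", "fc_threshold", "center_scope", "linkage")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop_named("unknown config keys: %s", paste(unknown, collapse = ", "))
  }
  seed <- config$seed %||% 1L
  alpha <- config$alpha %||% 0.05
  z_cut <- config$z_cut %||% 3.5
  q_level <- config$q_level %||% 0.05
  fc_threshold <- config$fc_threshold %||% 1
  center_scope <- config$center_scope %||% "all"
  linkage <- config$linkage %||% "complete"
  check_fraction(alpha, "alpha")
  check_fraction(q_level, "q_level")
  check_positive(z_cut, "z_cut")
  out_dir <- config$out_dir %||% stop_named("config needs 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  artifacts <- character(0)
  emit <- function(obj, name, writer = write_table_csv) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    artifacts <<- c(artifacts, p)
    p
  }

  withCallingHandlers({
    # stage 1: simulate the cohort and the drug plate
    cohort <- do.call(cohort_config,
                      c(config$cohort %||% list(), list(seed = seed)))
    sim <- simulate_digiwest_cohort(cohort)
    emit(sim$profiles, "profiles.csv")
    emit(sim$totals, "totals.csv")
    emit(sim$metadata, "metadata.csv")
    cyto_args <- c(config$cytotox %||% list(), list(seed = seed + 1L))
    cyto <- do.call(simulate_cytotox_plate, cyto_args)
    emit(cyto$table, "cytotox.csv")

    # stage 2: signal processing to the centered expression matrix
    em_raw <- build_afi_matrix(sim$profiles, sim$specs, sim$calibration,
                               samples = sim$metadata,
                               analytes = sim$analytes[, c("analyte_id",
                                                           "pathway")])
    em_norm <- normalize_total_protein(em_raw, sim$totals)
    em_imp <- impute_weak_signals(em_norm)
    em_log2 <- log2_transform(em_imp)
    em_cent <- median_center_log2(em_imp, scope = center_scope)
    emit(em_cent, "expression_centered.csv", write_expression_matrix)
    emit(attr(em_raw, "qc"), "lane_qc.csv")

    # stage 3: responder calling
    calls <- call_drug_response(cyto$table, alpha = alpha, z_cut = z_cut)
    emit(calls, "response_calls.csv")

    # stage 4: downstream statistics
    corr_overall <- pearson_pairs(em_log2, level = "overall_means")
    corr_protein <- pearson_pairs(em_log2, level = "per_protein")
    emit(rbind(cbind(level = "overall_means",
                     corr_overall[, c("r", "p", "n")],
                     id = NA_character_),
               cbind(level = "per_protein",
                     corr_protein[, c("r", "p", "n")],
                     id = corr_protein$analyte_id)),
         "correlations.csv")
    pdm <- sim$metadata$sample_id[sim$metadata$tissue == "PDM"]
    ptt <- sim$metadata$sample_id[sim$metadata$tissue == "PTT"]
    volcano <- welch_volcano(em_cent, pdm, ptt, q_threshold = q_level,
                             fc_threshold = fc_threshold)
    emit(volcano, "volcano.csv")
    cl <- hcl_cluster(select_samples(em_cent, pdm), axis = "samples",
                      linkage = linkage)
    emit(data.frame(sample_id = cl$samples$order,
                    position = seq_along(cl$samples$order)),
         "cluster_leaf_order.csv")
  }, warning = note)

  report <- list(
    package_version = as.character(utils::packageVersion("pdmtools")),
    seed = seed,
    parameters = list(alpha = alpha, z_cut = z_cut, q_level = q_level,
                      fc_threshold = fc_threshold,
                      center_scope = center_scope, linkage = linkage),
    warnings = warnings_log,
    outputs = lapply(artifacts, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
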