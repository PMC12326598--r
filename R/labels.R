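# Construction of sparse binary task matrices from assay potencies,
# continuous dose/time readouts, and ordinal histopathology severities.
#
# A "label matrix" throughout the package is a numeric matrix with values
# in {0, 1, NA}: rows are molecules (rownames = molecule ids), columns are
# tasks. NA means unmeasured; all counts and losses use observed entries
# only.

#' Validate and construct a sparse label matrix
#'
#' @param x numeric matrix with entries 0, 1 or `NA`.
#' @return the matrix, validated (invisibly classed as `label_matrix`).
#' @export
label_matrix <- function(x) {
  x <- as.matrix(x)
  v <- x[!is.na(x)]
  if (length(v) && !all(v %in% c(0, 1))) {
    stop("label matrix entries must be 0, 1 or NA")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("task", seq_len(ncol(x)))
  class(x) <- c("label_matrix", class(x))
  x
}

#' Convert IC50 (mol/L) to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the half-maximal inhibitory
#' concentration in mol/L: 1 uM corresponds to 6.0; 50 uM to ~4.3.
#'
#' @param ic50_molar positive concentration(s) in mol/L.
#' @return numeric pIC50 values.
#' @export
ic50_to_pic50 <- function(ic50_molar) {
  if (any(!is.finite(ic50_molar)) || any(ic50_molar <= 0)) {
    stop("IC50 must be a positive, finite concentration in mol/L")
  }
  -log10(ic50_molar)
}

#' Binarize a potency table against a pIC50 threshold
#'
#' An entry is active (1) iff its pIC50 is strictly greater than the
#' threshold, inactive (0) if measured and <= threshold, and `NA` when
#' unmeasured.
#'
#' @param pic50 numeric molecule x assay matrix with `NA` for unmeasured.
#' @param threshold pIC50 cutoff (finite scalar).
#' @return a [label_matrix()].
#' @export
binarize_potency <- function(pic50, threshold) {
  stopifnot(is.finite(threshold))
  pic50 <- as.matrix(pic50)
  out <- ifelse(is.na(pic50), NA_real_, as.numeric(pic50 > threshold))
  dimnames(out) <- dimnames(pic50)
  label_matrix(out)
}

#' Filter tasks by minimum class counts
#'
#' Keeps tasks with at least `min_pos` observed positives and `min_neg`
#' observed negatives, preserving column order. Typical settings are
#' 100/100 for large proprietary-scale panels and 10/10 for public panels.
#'
#' @param y a label matrix.
#' @param min_pos,min_neg minimum observed positive / negative counts.
#' @return the filtered [label_matrix()].
#' @export
filter_tasks <- function(y, min_pos, min_neg) {
  stopifnot(min_pos >= 0, min_neg >= 0)
  cnt <- label_counts(y)
  keep <- cnt[, "n_pos"] >= min_pos & cnt[, "n_neg"] >= min_neg
  if (!any(keep)) {
    rep <- paste(sprintf("%s: %d+/%d-", colnames(y), cnt[, 1], cnt[, 2]),
                 collapse = "; ")
    stop("all tasks filtered out; per-task counts: ", rep)
  }
  label_matrix(unclass(y)[, keep, drop = FALSE])
}

#' Construct a dose/time endpoint study table
#'
#' @param records data.frame with columns `molecule`, `endpoint`, `dose`,
#'   `time`, `value` (continuous readout or ordinal severity grade).
#' @param thresholds named numeric vector of per-endpoint cutoffs (e.g.
#'   fold-of-control elevation factors for biochemistry readouts).
#' @return object of class `endpoint_study`.
#' @export
endpoint_study <- function(records, thresholds = NULL) {
  need <- c("molecule", "endpoint", "dose", "time", "value")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  structure(list(records = records, thresholds = thresholds),
            class = "endpoint_study")
}

#' Load the default biochemistry elevation thresholds
#'
#' Ships fold-of-control elevation factors for the eight standard liver
#' biochemistry readouts (ALP, AST, ALT, GTP, TC, TG, TBIL, DBIL) in an
#' editable YAML config.
#'
#' @param path optional path to a user YAML; defaults to the packaged file.
#' @return named numeric vector.
#' @export
default_biochem_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "biochem_thresholds.yaml",
                        package = "vitroembed")
  }
  unlist(yaml::read_yaml(path))
}

#' Binarize continuous readouts by any-exceedance pooling
#'
#' A molecule is positive for an endpoint iff any of its dose/time records
#' exceeds the endpoint's expert threshold; negative if it has records and
#' none exceed; `NA` (missing) if it has no records for that endpoint.
#'
#' @param study an [endpoint_study()] with continuous `value`s; every
#'   endpoint present must have a threshold.
#' @param reducer `"any"` (default, exceedance at any dose/time) or
#'   `"max"` (identical outcome, expressed as max(value) > threshold);
#'   both are exposed because the pooling rule is a modeling choice.
#' @return a [label_matrix()], molecules x endpoints.
#' @export
binarize_readouts <- function(study, reducer = c("any", "max")) {
  stopifnot(inherits(study, "endpoint_study"))
  reducer <- match.arg(reducer)
  rec <- study$records
  eps <- unique(rec$endpoint)
  th <- study$thresholds
  if (is.null(th) || !all(eps %in% names(th))) {
    stop("missing threshold for endpoint(s): ",
         paste(setdiff(eps, names(th)), collapse = ", "))
  }
  mols <- unique(rec$molecule)
  out <- matrix(NA_real_, nrow = length(mols), ncol = length(eps),
                dimnames = list(mols, eps))
  agg <- stats::aggregate(value ~ molecule + endpoint, data = rec, FUN = max)
  for (i in seq_len(nrow(agg))) {
    out[agg$molecule[i], agg$endpoint[i]] <-
      as.numeric(agg$value[i] > th[[agg$endpoint[i]]])
  }
  label_matrix(out)
}

#' Pool ordinal histopathology severities into binary endpoints
#'
#' A molecule is positive for an endpoint iff its maximum severity grade
#' across all dose/time records reaches `min_severity`. Endpoint columns
#' observed positive in fewer than `min_compounds` unique molecules are
#' dropped (rare findings are not modelable).
#'
#' @param study an [endpoint_study()] whose `value`s are ordinal severity
#'   grades on a numeric scale (0 = no finding).
#' @param min_severity minimum grade counted as a positive (default 1).
#' @param min_compounds minimum unique positive molecules for an endpoint
#'   column to be retained (default 5).
#' @return a [label_matrix()].
#' @export
pool_histopathology <- function(study, min_severity = 1, min_compounds = 5L) {
  stopifnot(inherits(study, "endpoint_study"))
  rec <- study$records
  mols <- unique(rec$molecule)
  eps <- unique(rec$endpoint)
  out <- matrix(NA_real_, nrow = length(mols), ncol = length(eps),
                dimnames = list(mols, eps))
  agg <- stats::aggregate(value ~ molecule + endpoint, data = rec, FUN = max)
  for (i in seq_len(nrow(agg))) {
    out[agg$molecule[i], agg$endpoint[i]] <-
      as.numeric(agg$value[i] >= min_severity)
  }
  npos <- colSums(out == 1, na.rm = TRUE)
  label_matrix(out[, npos >= min_compounds, drop = FALSE])
}

#' Append an any-task aggregate endpoint
#'
#' Adds a global column that is 1 if any observed task is positive, 0 if
#' all observed tasks are negative, and `NA` if every task is unobserved
#' for that molecule. This is the construction behind global endpoints
#' such as an overall liver-injury flag.
#'
#' @param y a label matrix with at least one task.
#' @param name name of the appended column (default `"any_binary"`).
#' @return a [label_matrix()] with one extra column.
#' @export
aggregate_binary <- function(y, name = "any_binary") {
  stopifnot(ncol(y) >= 1)
  ym <- unclass(as.matrix(y))
  agg <- apply(ym, 1, function(r) {
    if (all(is.na(r))) NA_real_ else as.numeric(any(r == 1, na.rm = TRUE))
  })
  out <- cbind(ym, agg)
  colnames(out)[ncol(out)] <- name
  label_matrix(out)
}

#' Read / write a label matrix as CSV
#'
#' Format: a `molecule` identifier column plus one column per task; empty
#' cells are missing labels.
#'
#' @param path CSV file path.
#' @return a [label_matrix()] with molecule ids as rownames.
#' @export
read_label_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"molecule" %in% names(df)) stop("CSV must contain a `molecule` column")
  m <- as.matrix(df[, setdiff(names(df), "molecule"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$molecule
  label_matrix(m)
}

#' @rdname read_label_csv
#' @param y a label matrix.
#' @export
write_label_csv <- function(y, path) {
  df <- data.frame(molecule = rownames(y), unclass(as.matrix(y)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Read an endpoint study from long-format CSV
#'
#' @param path CSV with columns `molecule`, `endpoint`, `dose`, `time`,
#'   `value`.
#' @param thresholds optional named numeric vector of per-endpoint cutoffs.
#' @return an [endpoint_study()].
#' @export
read_endpoint_csv <- function(path, thresholds = NULL) {
  endpoint_study(utils::read.csv(path, stringsAsFactors = FALSE), thresholds)
}
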