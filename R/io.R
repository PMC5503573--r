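# Feature-matrix and sample-table containers and their tab-delimited I/O.
#
# A feature matrix is a base numeric matrix, samples in rows and spectral
# ions in columns; rownames are sample ids, colnames are canonical ion
# labels (see ion_label).  Intensities are nonnegative and 0 means "not
# detected".  A sample table is a data.frame with columns sample_id,
# group ("case"/"control") and split ("train"/"test").

#' Validate a feature matrix
#'
#' Checks the container contract: numeric matrix, no negative entries, no
#' missing values, unique sample ids and unique canonical ion labels.
#'
#' @param x Numeric matrix, samples x ions, with dimnames.
#' @return `x`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_feature_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    ms_stop("feature matrix must be a numeric matrix", "format_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    ms_stop("feature matrix must have sample ids (rownames) and ion labels (colnames)",
            "format_error")
  }
  if (anyNA(x)) ms_stop("feature matrix contains missing values", "format_error")
  if (any(x < 0)) ms_stop("feature matrix contains negative intensities", "format_error")
  if (anyDuplicated(rownames(x))) ms_stop("duplicate sample ids", "format_error")
  if (anyDuplicated(colnames(x))) ms_stop("duplicate ion labels", "format_error")
  parse_ion_label(colnames(x))
  invisible(x)
}

#' Validate a sample table against a feature matrix
#'
#' @param samples data.frame with columns `sample_id`, `group`
#'   (`"case"`/`"control"`) and `split` (`"train"`/`"test"`).
#' @param matrix Optional feature matrix; if given, every matrix sample must
#'   appear exactly once in the table.
#' @return `samples`, invisibly.
#' @export
validate_sample_table <- function(samples, matrix = NULL) {
  need <- c("sample_id", "group", "split")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    ms_stop("sample table needs columns sample_id, group, split", "format_error")
  }
  if (!all(samples$group %in% c("case", "control"))) {
    ms_stop("group must be 'case' or 'control'", "format_error")
  }
  if (!all(samples$split %in% c("train", "test"))) {
    ms_stop("split must be 'train' or 'test'", "format_error")
  }
  if (anyDuplicated(samples$sample_id)) {
    ms_stop("duplicate sample ids in sample table", "format_error")
  }
  if (!is.null(matrix) && !setequal(rownames(matrix), samples$sample_id)) {
    ms_stop("sample table and feature matrix disagree on sample ids", "format_error")
  }
  invisible(samples)
}

# fixed-notation formatting with up to 12 significant digits; round-trip
# stable through as.numeric at that precision
format_intensity <- function(x) {
  out <- formatC(x, format = "fg", digits = 12, width = 1L)
  gsub(" ", "", out, fixed = TRUE)
}

#' Read and write feature matrices
#'
#' Tab-delimited text with a header row of canonical ion labels and the
#' sample id in the first column.  Intensities are written in fixed notation
#' with up to 12 significant digits, so a write/read round trip preserves
#' values to that precision and preserves row/column order exactly.
#'
#' @param path File path.
#' @param matrix Feature matrix (see [validate_feature_matrix()]).
#' @return `read_matrix()` returns the feature matrix; `write_matrix()`
#'   returns `path` invisibly.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) ms_stop("matrix file has no data rows", "format_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L || header[1L] != "sample_id") {
    ms_stop("line 1: header must start with 'sample_id'", "format_error")
  }
  ions <- header[-1L]
  if (anyDuplicated(ions)) {
    ms_stop(sprintf("line 1: duplicate ion label '%s'", ions[duplicated(ions)][1L]),
            "format_error")
  }
  parse_ion_label(ions)
  n_ion <- length(ions)
  body <- fields[-1L]
  len <- lengths(body)
  if (any(len != n_ion + 1L)) {
    bad <- which(len != n_ion + 1L)[1L]
    ms_stop(sprintf("line %d: expected %d fields, found %d",
                    bad + 1L, n_ion + 1L, len[bad]), "format_error")
  }
  ids <- vapply(body, `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    ms_stop(sprintf("line %d: duplicate sample id '%s'",
                    which(duplicated(ids))[1L] + 1L, ids[duplicated(ids)][1L]),
            "format_error")
  }
  vals <- suppressWarnings(
    as.numeric(unlist(lapply(body, `[`, -1L), use.names = FALSE))
  )
  m <- matrix(vals, nrow = length(body), ncol = n_ion, byrow = TRUE,
              dimnames = list(ids, ions))
  bad_row <- which(apply(is.na(m) | m < 0, 1L, any))
  if (length(bad_row)) {
    ms_stop(sprintf("line %d: negative or non-numeric intensity",
                    bad_row[1L] + 1L), "format_error")
  }
  m
}

#' @rdname read_matrix
#' @export
write_matrix <- function(matrix, path) {
  validate_feature_matrix(matrix)
  header <- paste(c("sample_id", colnames(matrix)), collapse = "\t")
  chr <- matrix(format_intensity(matrix), nrow = nrow(matrix))
  rows <- paste(rownames(matrix),
                apply(chr, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read and write sample tables
#'
#' Tab-delimited with columns `sample_id`, `group`, `split`.
#'
#' @param samples Sample table data.frame.
#' @param path File path.
#' @return `read_samples()` returns the sample table data.frame;
#'   `write_samples()` returns `path` invisibly.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_table(df)
  df
}

#' @rdname read_samples
#' @export
write_samples <- function(samples, path) {
  validate_sample_table(samples)
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Randomly assigns the requested number of case and control samples to the
#' training split; the remainder form the test split.  Assignment is
#' stratified by group and deterministic under `seed`.
#'
#' @param samples Sample table (its existing `split` column, if any, is
#'   overwritten).
#' @param n_case_train,n_control_train Training-set size per group.
#' @param seed Integer seed.
#' @return The sample table with an updated `split` column.
#' @examples
#' st <- data.frame(sample_id = paste0("s", 1:152),
#'                  group = rep(c("case", "control"), c(87, 65)),
#'                  split = "train")
#' st <- split_train_test(st, 55, 50, seed = 1)
#' table(st$group, st$split) # 32 case / 15 control in the test split
#' @export
split_train_test <- function(samples, n_case_train, n_control_train, seed = 1L) {
  stopifnot_scalar_count(n_case_train, "n_case_train")
  stopifnot_scalar_count(n_control_train, "n_control_train")
  n_case <- sum(samples$group == "case")
  n_control <- sum(samples$group == "control")
  if (n_case_train > n_case || n_control_train > n_control) {
    ms_stop("requested training counts exceed available samples per group",
            "argument_error")
  }
  with_seed(seed, {
    samples$split <- "test"
    idx_case <- sample_vec(which(samples$group == "case"), n_case_train)
    idx_ctrl <- sample_vec(which(samples$group == "control"), n_control_train)
    samples$split[c(idx_case, idx_ctrl)] <- "train"
  })
  samples
}
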