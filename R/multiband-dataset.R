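#' Multi-band dataset container
#'
#' Bundles one feature matrix per frequency band together with class labels.
#' Every matrix is `d x n` with features in rows and samples in columns;
#' column `j` of every band refers to the same sample (epoch), so the bands
#' share the sample axis. Labels are remapped to contiguous integers
#' `1..C` in order of first appearance; the original label values are kept
#' in `label_values` for reporting.
#'
#' @param Z list of numeric matrices, one per band, all `d x n`
#'   (features in rows, samples in columns).
#' @param labels integer-valued vector of length `n` giving the class of
#'   each sample; any integer values are accepted and remapped to `1..C`.
#' @param band_names optional character vector naming the bands; defaults
#'   to names of `Z` or `"band1"`, `"band2"`, ...
#'
#' @return An object of class `multiband_dataset`: a list with elements
#'   `Z` (list of `d x n` matrices), `labels` (integers in `1..C`),
#'   `label_values` (original value for each class index), `band_names`,
#'   and counts `M`, `d`, `n`, `C`.
#' @examples
#' Z <- replicate(2, matrix(rnorm(40), 4, 10), simplify = FALSE)
#' ds <- multiband_dataset(Z, labels = rep(c(3, 7), each = 5))
#' ds$C        # 2: labels 3 and 7 remapped to 1 and 2
#' @export
multiband_dataset <- function(Z, labels, band_names = NULL) {
  if (!is.list(Z) || length(Z) < 1L)
    stop("`Z` must be a non-empty list of matrices (one per band)")
  Z <- lapply(Z, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  dims <- vapply(Z, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent band shapes: all bands must be d x n with identical d and n")
  d <- unname(dims[1, 1])
  n <- unname(dims[2, 1])
  if (d < 1L || n < 1L) stop("bands must have at least one feature and one sample")
  if (anyNA(labels)) stop("labels must not contain NA")
  labels <- as.vector(labels)
  if (length(labels) != n)
    stop(sprintf("label/sample mismatch: %d labels for %d samples", length(labels), n))
  if (any(labels != round(labels))) stop("labels must be integers")
  label_values <- unique(labels)          # order of first appearance
  lab <- match(labels, label_values)
  C <- length(label_values)
  if (is.null(band_names)) band_names <- names(Z)
  if (is.null(band_names)) band_names <- paste0("band", seq_along(Z))
  if (length(band_names) != length(Z))
    stop("`band_names` must have one entry per band")
  names(Z) <- band_names
  structure(
    list(Z = Z, labels = as.integer(lab), label_values = label_values,
         band_names = as.character(band_names),
         M = length(Z), d = d, n = n, C = C),
    class = "multiband_dataset"
  )
}

#' @export
print.multiband_dataset <- function(x, ...) {
  cat(sprintf("<multiband_dataset> %d band(s) x %d features x %d samples, %d class(es)\n",
              x$M, x$d, x$n, x$C))
  cat("  bands:  ", paste(x$band_names, collapse = ", "), "\n", sep = "")
  tab <- table(factor(x$labels, levels = seq_len(x$C)))
  cat("  classes:", paste(sprintf("%s (n=%d)", x$label_values, tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subset a multi-band dataset by sample index
#'
#' Selects the same columns from every band; labels follow. Class indices
#' are re-derived, so a subset that drops a class entirely gets contiguous
#' labels again.
#'
#' @param ds a [multiband_dataset()].
#' @param idx integer vector of sample (column) indices.
#' @return A `multiband_dataset` with `length(idx)` samples.
#' @export
subset_samples <- function(ds, idx) {
  stopifnot(inherits(ds, "multiband_dataset"))
  idx <- as.integer(idx)
  if (length(idx) < 1L || any(idx < 1L) || any(idx > ds$n))
    stop("sample indices out of range")
  multiband_dataset(lapply(ds$Z, function(m) m[, idx, drop = FALSE]),
                    labels = ds$label_values[ds$labels[idx]],
                    band_names = ds$band_names)
}

# sniff the delimiter of a delimited text matrix: comma or tab
detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

read_matrix_file <- function(path, header = FALSE) {
  sep <- detect_sep(path)
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = header, colClasses = "numeric",
                      comment.char = "", blank.lines.skip = TRUE),
    error = function(e) stop(sprintf("failed to parse '%s' as a numeric matrix: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  as.matrix(df)
}

#' Read a multi-band dataset from delimited text files
#'
#' Each band file is a `d x n` numeric matrix (features in rows, samples in
#' columns) in comma- or tab-separated text (delimiter auto-detected per
#' file, `.` decimal). The label file holds one integer per line, one per
#' sample column. Labels are remapped to contiguous `1..C`.
#'
#' @param band_paths character vector of band file paths (band order
#'   follows this vector).
#' @param labels_path path to the label file.
#' @param band_names optional band names; defaults to band file base names.
#' @param header logical; skip one header row in the band files.
#' @return A [multiband_dataset()].
#' @export
load_multiband_dataset <- function(band_paths, labels_path, band_names = NULL,
                                   header = FALSE) {
  if (length(band_paths) < 1L) stop("at least one band file is required")
  Z <- lapply(band_paths, read_matrix_file, header = header)
  dims <- vapply(Z, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop(sprintf(
      "inconsistent band shapes: %s",
      paste(sprintf("%s is %dx%d", basename(band_paths), dims[1, ], dims[2, ]),
            collapse = ", ")))
  labels <- scan(labels_path, what = integer(), quiet = TRUE)
  if (length(labels) != dims[2, 1])
    stop(sprintf("label/sample mismatch: %d labels in '%s' for %d sample columns",
                 length(labels), labels_path, dims[2, 1]))
  if (is.null(band_names))
    band_names <- sub("\\.[^.]*$", "", basename(band_paths))
  multiband_dataset(Z, labels, band_names = band_names)
}

#' Write a multi-band dataset as delimited text files
#'
#' Inverse of [load_multiband_dataset()]: one CSV per band (features in
#' rows, samples in columns, no header) plus a label file with one integer
#' per line. Original label values are written, so a load/save round trip
#' reproduces the dataset.
#'
#' @param ds a [multiband_dataset()].
#' @param dir output directory (created if missing).
#' @param digits significant digits for matrix entries; the default keeps
#'   full double precision so round trips are exact.
#' @return Invisibly, a list with `band_paths` and `labels_path`.
#' @export
write_multiband_dataset <- function(ds, dir, digits = 17L) {
  stopifnot(inherits(ds, "multiband_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  band_paths <- file.path(dir, paste0(ds$band_names, ".csv"))
  for (m in seq_len(ds$M)) {
    txt <- apply(ds$Z[[m]], 1L, function(r)
      paste(formatC(r, digits = digits, format = "g"), collapse = ","))
    writeLines(txt, band_paths[m])
  }
  labels_path <- file.path(dir, "labels.txt")
  writeLines(as.character(ds$label_values[ds$labels]), labels_path)
  invisible(list(band_paths = band_paths, labels_path = labels_path))
}

#' Stratified train/test split
#'
#' Splits the sample columns into train and test sets, preserving per-class
#' proportions to within one sample. Within each class,
#' `round(train_fraction * n_c)` samples go to train, but at least one
#' sample per class is kept on each side. Deterministic given `seed`.
#'
#' @param ds a [multiband_dataset()].
#' @param train_fraction fraction of samples per class assigned to train,
#'   in (0, 1).
#' @param seed integer seed for the random within-class assignment.
#' @return A list with elements `train` and `test`
#'   (both [multiband_dataset()]) and the index vectors `train_idx`,
#'   `test_idx` (a partition of `1..n`).
#' @export
stratified_split <- function(ds, train_fraction, seed) {
  stopifnot(inherits(ds, "multiband_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie strictly between 0 and 1")
  counts <- tabulate(ds$labels, nbins = ds$C)
  if (any(counts < 2L))
    stop(sprintf("class %s has only one sample; cannot split",
                 ds$label_values[which(counts < 2L)[1]]))
  train_idx <- integer(0)
  with_seed(seed, {
    for (c in seq_len(ds$C)) {
      members <- which(ds$labels == c)
      n_c <- length(members)
      k <- round(train_fraction * n_c)
      k <- max(1L, min(n_c - 1L, k))   # keep >=1 sample on each side
      train_idx <- c(train_idx, sample(members, k))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(ds$n), train_idx)
  list(train = subset_samples(ds, train_idx),
       test = subset_samples(ds, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Per-feature z-scoring across bands
#'
#' Optionally standardizes each feature (row) of each band to zero mean and
#' unit variance using statistics from a reference dataset (typically the
#' training split), returning both the scaled data and the statistics so a
#' test set can be scaled consistently.
#'
#' @param ds a [multiband_dataset()] to scale.
#' @param stats optional list of per-band `mean`/`sd` matrices as returned
#'   in the `stats` element; if `NULL`, computed from `ds`.
#' @return A list with `data` (scaled `multiband_dataset`) and `stats`.
#' @export
zscore_features <- function(ds, stats = NULL) {
  stopifnot(inherits(ds, "multiband_dataset"))
  if (is.null(stats)) {
    stats <- lapply(ds$Z, function(m) {
      s <- apply(m, 1L, stats::sd)
      list(mean = rowMeans(m), sd = ifelse(s > 0, s, 1))
    })
  }
  Z <- Map(function(m, st) (m - st$mean) / st$sd, ds$Z, stats)
  list(data = multiband_dataset(Z, ds$label_values[ds$labels], ds$band_names),
       stats = stats)
}

# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
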