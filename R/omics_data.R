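#' Multi-omics dataset with block structure
#'
#' Container for a samples x features numeric matrix partitioned into named
#' omics blocks (e.g. `rs`, `cn`, `mu`, `pp`), an observation mask, and an
#' optional binary outcome. Block-wise missingness means a sample's cells are
#' missing for entire blocks at a time; the mask records observation status
#' cell-by-cell and downstream profiling enforces block-constancy.
#'
#' Masked cells may still carry values in `values` (e.g. after controlled
#' missingness injection, where the underlying truth is hidden rather than
#' destroyed); all computation must read data through [masked_values()],
#' which returns `NA` wherever the mask is `FALSE`.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   column names. `NA` entries are treated as unobserved.
#' @param blocks named list mapping block name to the character vector of its
#'   feature (column) ids, in the fixed block order.
#' @param labels optional integer vector of 0/1 outcomes (1 = minority /
#'   positive class, e.g. deceased), one per sample.
#' @param mask optional logical matrix, `TRUE` = observed; defaults to
#'   `!is.na(values)`.
#' @param sample_ids optional character vector of unique sample identifiers;
#'   defaults to rownames of `values` or `s1..sn`.
#' @return An object of class `multiomics_dataset` with elements `values`,
#'   `mask`, `blocks` (list of `block_spec`), `labels`, `sample_ids`.
#' @examples
#' x <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, c("g1", "g2", "p1", "p2")))
#' ds <- multiomics_dataset(x, blocks = list(rs = c("g1", "g2"), pp = c("p1", "p2")))
#' n_samples(ds)
#' @export
multiomics_dataset <- function(values, blocks, labels = NULL, mask = NULL,
                               sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) {
    stop("`values` must have feature ids as column names")
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature ids in `values`")
  }
  if (!is.list(blocks) || is.null(names(blocks)) || any(names(blocks) == "")) {
    stop("`blocks` must be a named list of feature-id vectors")
  }
  feats <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(feats)) {
    stop("feature ids appear in more than one block: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  missing_feats <- setdiff(feats, colnames(values))
  if (length(missing_feats)) {
    stop("features listed in blocks but absent from matrix: ",
         paste(head(missing_feats, 5), collapse = ", "))
  }
  orphan <- setdiff(colnames(values), feats)
  if (length(orphan)) {
    stop("matrix columns not covered by any block: ",
         paste(head(orphan, 5), collapse = ", "))
  }
  if (any(lengths(blocks) == 0L)) stop("every block must list >= 1 feature")
  # column order follows block order
  values <- values[, feats, drop = FALSE]
  if (is.null(mask)) {
    mask <- !is.na(values)
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(values))) {
      stop("`mask` and `values` must have identical shape")
    }
    mask <- mask[, feats, drop = FALSE] |> apply(2, as.logical)
    dim(mask) <- dim(values)
  }
  dimnames(mask) <- dimnames(values)
  n <- nrow(values)
  sample_ids <- sample_ids %||% rownames(values) %||% paste0("s", seq_len(n))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(sample_ids) != n) stop("sample_ids length mismatch")
  rownames(values) <- rownames(mask) <- sample_ids
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("labels length mismatch")
    if (!all(labels %in% c(0L, 1L))) stop("labels must be coded 0/1")
  }
  specs <- vector("list", length(blocks))
  names(specs) <- names(blocks)
  for (i in seq_along(blocks)) {
    specs[[i]] <- structure(
      list(name = names(blocks)[i], feature_ids = blocks[[i]],
           position = i - 1L),
      class = "block_spec")
  }
  structure(
    list(values = values, mask = mask, blocks = specs, labels = labels,
         sample_ids = sample_ids),
    class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("multiomics_dataset: %d samples x %d features, %d blocks (%s)\n",
              nrow(x$values), ncol(x$values), length(x$blocks),
              paste(names(x$blocks), collapse = ", ")))
  cat(sprintf("  observed cells: %.1f%%\n", 100 * mean(x$mask)))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d negative / %d positive\n",
                sum(x$labels == 0L), sum(x$labels == 1L)))
  }
  invisible(x)
}

#' Number of samples / blocks in a dataset
#' @param ds a `multiomics_dataset`
#' @return integer count
#' @export
n_samples <- function(ds) nrow(ds$values)

#' @rdname n_samples
#' @export
n_blocks <- function(ds) length(ds$blocks)

#' Feature ids of selected blocks
#' @param ds a `multiomics_dataset`
#' @param block_names character vector of block names; defaults to all blocks
#' @return character vector of feature ids in block order
#' @export
block_features <- function(ds, block_names = names(ds$blocks)) {
  unlist(lapply(ds$blocks[block_names], `[[`, "feature_ids"), use.names = FALSE)
}

#' Values with masked cells set to NA
#'
#' The only sanctioned way to read data out of a [multiomics_dataset()]:
#' unobserved cells are `NA` regardless of what the `values` slot carries.
#' @param ds a `multiomics_dataset`
#' @return numeric matrix with `NA` in unobserved cells
#' @export
masked_values <- function(ds) {
  v <- ds$values
  v[!ds$mask] <- NA_real_
  v
}

#' Subset a dataset by sample index
#' @param ds a `multiomics_dataset`
#' @param idx integer or logical sample index
#' @return a `multiomics_dataset` with the selected samples
#' @export
subset_samples <- function(ds, idx) {
  multiomics_dataset(
    values = ds$values[idx, , drop = FALSE],
    blocks = block_feature_list(ds),
    labels = if (!is.null(ds$labels)) ds$labels[idx],
    mask = ds$mask[idx, , drop = FALSE],
    sample_ids = ds$sample_ids[idx])
}

block_feature_list <- function(ds) {
  lapply(ds$blocks, `[[`, "feature_ids")
}

#' Read a multi-omics dataset from delimited text files
#'
#' @param features_path delimited text (comma or tab; auto-detected from the
#'   header line), first column sample id, remaining columns features. Empty
#'   fields and the literal `NA` are read as missing.
#' @param manifest_path block manifest: two tab/comma-separated columns
#'   `block` and `feature`, one row per feature, block order given by first
#'   appearance.
#' @param labels_path optional two-column delimited text (sample id, 0/1).
#' @return a [multiomics_dataset()]
#' @seealso [write_multiomics()]
#' @export
read_multiomics <- function(features_path, manifest_path, labels_path = NULL) {
  for (p in c(features_path, manifest_path, labels_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  sep_of <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("\t", first)) "\t" else ","
  }
  feat <- read.delim(features_path, sep = sep_of(features_path),
                     check.names = FALSE, na.strings = c("", "NA"),
                     stringsAsFactors = FALSE)
  ids <- as.character(feat[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in features file: ",
         ids[duplicated(ids)][1])
  }
  vals <- as.matrix(feat[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  man <- read.delim(manifest_path, sep = sep_of(manifest_path),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("block", "feature") %in% names(man))) {
    stop("manifest must have columns `block` and `feature`")
  }
  absent <- setdiff(man$feature, colnames(vals))
  if (length(absent)) {
    stop("manifest features absent from matrix: ",
         paste(head(absent, 5), collapse = ", "))
  }
  blocks <- split(man$feature, factor(man$block, levels = unique(man$block)))
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- read.delim(labels_path, sep = sep_of(labels_path),
                      check.names = FALSE, stringsAsFactors = FALSE)
    lab_ids <- as.character(lab[[1]])
    unknown <- setdiff(lab_ids, ids)
    if (length(unknown)) {
      stop("label sample ids not present in feature matrix: ",
           paste(head(unknown, 5), collapse = ", "))
    }
    if (!setequal(lab_ids, ids)) {
      stop("labels file must cover every sample in the feature matrix")
    }
    labels <- as.integer(lab[[2]])[match(ids, lab_ids)]
  }
  multiomics_dataset(vals, blocks = as.list(blocks), labels = labels,
                     sample_ids = ids)
}

#' Write a multi-omics dataset as a features/manifest/labels file triple
#'
#' Missing (masked) cells are written as the literal `NA`. Round-trips with
#' [read_multiomics()] on values, mask, block order and labels.
#'
#' @param ds a [multiomics_dataset()]
#' @param features_path,manifest_path,labels_path output paths; labels are
#'   only written when the dataset has them and `labels_path` is given.
#' @param sep field separator (default tab)
#' @return invisibly, the paths written
#' @export
write_multiomics <- function(ds, features_path, manifest_path,
                             labels_path = NULL, sep = "\t") {
  df <- data.frame(sample_id = ds$sample_ids, masked_values(ds),
                   check.names = FALSE)
  write.table(df, features_path, sep = sep, row.names = FALSE,
              quote = FALSE, na = "NA")
  man <- data.frame(
    block = rep(names(ds$blocks), lengths(block_feature_list(ds))),
    feature = unlist(block_feature_list(ds), use.names = FALSE))
  write.table(man, manifest_path, sep = sep, row.names = FALSE, quote = FALSE)
  paths <- c(features_path, manifest_path)
  if (!is.null(labels_path) && !is.null(ds$labels)) {
    write.table(data.frame(sample_id = ds$sample_ids, label = ds$labels),
                labels_path, sep = sep, row.names = FALSE, quote = FALSE)
    paths <- c(paths, labels_path)
  }
  invisible(paths)
}

#' Fit a per-feature min-max scaler on observed values
#'
#' @param values numeric matrix with `NA` for unobserved cells
#' @return object of class `minmax_scaler` with per-feature `min` and `max`
#' @details Features observed nowhere in the fit data are an error (there is
#'   nothing to anchor the scale to). Constant features are retained; they
#'   normalize to 0 by convention (deterministic alternative to dividing by a
#'   zero range).
#' @export
minmax_fit <- function(values) {
  values <- as.matrix(values)
  n_obs <- colSums(!is.na(values))
  if (any(n_obs == 0L)) {
    stop("feature(s) with zero observed values in fit data: ",
         paste(head(colnames(values)[n_obs == 0L], 5), collapse = ", "))
  }
  structure(
    list(min = apply(values, 2, min, na.rm = TRUE),
         max = apply(values, 2, max, na.rm = TRUE)),
    class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Observed values map to `(x - min) / (max - min)`; values outside the fitted
#' range map linearly (no clipping, so results may fall outside `[0, 1]`);
#' constant features map to 0; `NA` cells pass through unchanged.
#'
#' @param scaler a `minmax_scaler` from [minmax_fit()]
#' @param values numeric matrix whose columns match the scaler's features
#' @return normalized matrix, same shape and `NA` pattern as `values`
#' @export
minmax_apply <- function(scaler, values) {
  values <- as.matrix(values)
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), names(scaler$min))) {
    values <- values[, names(scaler$min), drop = FALSE]
  }
  rng <- scaler$max - scaler$min
  out <- sweep(values, 2, scaler$min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out[is.na(values)] <- NA_real_
  out
}

#' Invert a fitted min-max scaler
#' @param scaler a `minmax_scaler`
#' @param values normalized matrix
#' @return matrix on the original scale (constant features restored to their
#'   fitted minimum)
#' @export
minmax_invert <- function(scaler, values) {
  values <- as.matrix(values)
  rng <- scaler$max - scaler$min
  out <- sweep(sweep(values, 2, rng, "*"), 2, scaler$min, "+")
  out
}

#' Fit-and-apply min-max normalization
#'
#' Convenience wrapper: fits the scaler on `fit_values` (training data) and
#' applies it to `apply_values` (e.g. held-out test data), so normalization
#' statistics never leak from test to train.
#'
#' @param fit_values matrix the scaler is fitted on (observed values only)
#' @param apply_values matrix to normalize
#' @return list with `normalized` matrix and the fitted `scaler`
#' @export
minmax_fit_apply <- function(fit_values, apply_values = fit_values) {
  scaler <- minmax_fit(fit_values)
  list(normalized = minmax_apply(scaler, apply_values), scaler = scaler)
}

#' Stratified train/test split
#'
#' Reserves `round(n_class * test_fraction)` samples per class (half away
#' from zero, floor of 1 per class) for testing, sampling without
#' replacement, driven only by `seed`.
#'
#' @param ds a labelled [multiomics_dataset()]
#' @param test_fraction fraction in (0, 1)
#' @param seed integer seed
#' @return list with `train` and `test` datasets (disjoint, union = `ds`)
#' @export
stratified_split <- function(ds, test_fraction, seed) {
  if (is.null(ds$labels)) stop("stratified_split requires labels")
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)")
  }
  counts <- table(factor(ds$labels, levels = c(0L, 1L)))
  if (any(counts < 2L)) {
    stop("each class needs >= 2 samples to split; counts: ",
         paste(counts, collapse = "/"))
  }
  test_idx <- integer(0)
  withr::with_seed(seed, {
    for (cl in c(0L, 1L)) {
      members <- which(ds$labels == cl)
      n_test <- max(1L, as.integer(round_half_away(length(members) * test_fraction)))
      n_test <- min(n_test, length(members) - 1L)
      test_idx <- c(test_idx, sample(members, n_test))
    }
  })
  test_idx <- sort(test_idx)
  list(train = subset_samples(ds, setdiff(seq_len(n_samples(ds)), test_idx)),
       test = subset_samples(ds, test_idx))
}

#' Balance classes by randomly duplicating minority rows
#'
#' Appends uniformly resampled (with replacement) copies of minority-class
#' rows until both classes match the majority count. Original rows are all
#' retained, in order, ahead of the duplicates.
#'
#' @param features numeric matrix (rows = samples)
#' @param labels 0/1 vector, both classes present
#' @param seed integer seed
#' @return list with balanced `features` and `labels`
#' @export
oversample_minority <- function(features, labels, seed) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab == 0L)) stop("oversample_minority requires both classes")
  if (tab[1] == tab[2]) {
    return(list(features = features, labels = labels))
  }
  minority <- if (tab["1"] < tab["0"]) 1L else 0L
  need <- abs(diff(as.integer(tab)))
  pool <- which(labels == minority)
  extra <- withr::with_seed(seed, sample(pool, need, replace = TRUE))
  list(features = rbind(features, features[extra, , drop = FALSE]),
       labels = c(labels, labels[extra]))
}
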