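#' Construct a paired transcript/protein data set
#'
#' Both layers are features-by-samples numeric matrices and must share the
#' same feature identifiers (row names) and sample identifiers (column
#' names), in the same order. Abundances are nonnegative; `NA` marks a
#' missing measurement (zeros are valid observations, not missing).
#'
#' @param transcript features x samples matrix of transcript abundances
#'   (FPKM-like scale).
#' @param protein features x samples matrix of protein abundances.
#' @return object of class `paired_omics` with elements `transcript` and
#'   `protein`.
#' @export
paired_omics <- function(transcript, protein) {
  transcript <- as.matrix(transcript)
  protein <- as.matrix(protein)
  for (m in list(transcript, protein)) {
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop("layers must carry feature row names and sample column names")
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
      stop("feature and sample identifiers must be unique")
  }
  if (!identical(rownames(transcript), rownames(protein)))
    stop("layers must share identical feature identifiers in the same order")
  if (!identical(colnames(transcript), colnames(protein)))
    stop("layers must share identical sample identifiers in the same order")
  structure(list(transcript = transcript, protein = protein),
            class = "paired_omics")
}

#' @export
print.paired_omics <- function(x, ...) {
  cat(sprintf("paired_omics: %d features x %d samples (transcript + protein)\n",
              nrow(x$transcript), ncol(x$transcript)))
  invisible(x)
}

#' Number of features / samples in a paired data set
#' @param data a `paired_omics`.
#' @return integer count.
#' @export
n_features <- function(data) nrow(data$transcript)

#' @rdname n_features
#' @export
n_samples <- function(data) ncol(data$transcript)

#' Subset both layers to a set of features
#'
#' @param data a `paired_omics`.
#' @param keep logical mask or feature identifiers.
#' @return a `paired_omics` with the selected features, order preserved.
#' @export
subset_features <- function(data, keep) {
  paired_omics(data$transcript[keep, , drop = FALSE],
               data$protein[keep, , drop = FALSE])
}

#' Keep only feature pairs observed in every sample of both layers
#'
#' A feature survives only when it has no missing value in any sample at
#' either the transcript or the protein level. This is the first filtering
#' step of the pipeline; an empty result is legal and triggers a warning.
#'
#' @param data a `paired_omics`.
#' @return filtered `paired_omics`, feature order preserved.
#' @export
filter_complete_pairs <- function(data) {
  stopifnot(inherits(data, "paired_omics"))
  keep <- stats::complete.cases(data$transcript) &
    stats::complete.cases(data$protein)
  if (!any(keep)) warning("no feature has complete observations in both layers")
  subset_features(data, keep)
}

#' Keep features expressed above a threshold in enough samples
#'
#' Retains feature pairs whose abundance is strictly greater than
#' `threshold` in at least `min_samples` samples in the transcript layer AND
#' at least `min_samples` samples in the protein layer. The default
#' `min_samples` is one third of the samples (rounded up), e.g. 5 of 15
#' tissues. Missing values never count as exceeding the threshold.
#'
#' @param data a `paired_omics`.
#' @param threshold abundance cutoff (strict inequality); default 1.
#' @param min_samples minimum number of qualifying samples per layer;
#'   default `ceiling(n_samples / 3)`.
#' @return filtered `paired_omics`.
#' @export
filter_min_expression <- function(data, threshold = 1,
                                  min_samples = ceiling(n_samples(data) / 3)) {
  stopifnot(inherits(data, "paired_omics"))
  if (min_samples <= 0) stop("min_samples must be positive")
  if (min_samples > n_samples(data)) stop("min_samples exceeds sample count")
  count_pass <- function(m) rowSums(m > threshold, na.rm = TRUE)
  keep <- count_pass(data$transcript) >= min_samples &
    count_pass(data$protein) >= min_samples
  subset_features(data, keep)
}

#' Flag features usable for network construction
#'
#' A feature qualifies only when, in both layers, it has no missing value
#' and nonzero variance across samples (constant profiles carry no
#' correlation information).
#'
#' @param data a `paired_omics`.
#' @return logical vector over features, `TRUE` = usable.
#' @export
good_features <- function(data) {
  stopifnot(inherits(data, "paired_omics"))
  ok_layer <- function(m) {
    complete <- stats::complete.cases(m)
    v <- apply(m, 1, function(x) stats::var(x, na.rm = TRUE))
    complete & !is.na(v) & v > 0
  }
  out <- ok_layer(data$transcript) & ok_layer(data$protein)
  names(out) <- rownames(data$transcript)
  out
}

#' Per-pair Spearman correlation between transcript and protein profiles
#'
#' For every feature, the Spearman rank correlation between its transcript
#' profile and its protein profile across samples (average ranks for ties),
#' plus summary statistics: the mean coefficient and the count of positive
#' coefficients. Run after filtering; missing values are not accepted.
#'
#' @param data a complete (no `NA`) `paired_omics` with at least 3 samples.
#' @return list of class `pair_correlation_summary` with `per_pair_rho`,
#'   `mean_rho`, `n_positive`, `n_total`.
#' @export
pair_spearman_summary <- function(data) {
  stopifnot(inherits(data, "paired_omics"))
  if (n_samples(data) < 3) stop("at least 3 samples are required")
  if (anyNA(data$transcript) || anyNA(data$protein))
    stop("missing values present; apply filter_complete_pairs first")
  rho <- vapply(seq_len(n_features(data)), function(i) {
    stats::cor(data$transcript[i, ], data$protein[i, ], method = "spearman")
  }, numeric(1))
  names(rho) <- rownames(data$transcript)
  structure(list(per_pair_rho = rho,
                 mean_rho = mean(rho),
                 n_positive = sum(rho > 0),
                 n_total = length(rho)),
            class = "pair_correlation_summary")
}

#' @export
print.pair_correlation_summary <- function(x, ...) {
  cat(sprintf("pair_correlation_summary: %d pairs, mean rho %.3f, %d positive (%.1f%%)\n",
              x$n_total, x$mean_rho, x$n_positive,
              100 * x$n_positive / max(1, x$n_total)))
  invisible(x)
}

#' Run the full filtering chain with a per-step report
#'
#' Applies, in order: complete-pairs filter, minimum-expression filter, and
#' the good-features mask. Returns the filtered data together with a table
#' of feature counts after each step, suitable for provenance logging.
#'
#' @inheritParams filter_min_expression
#' @return list with `data` (filtered `paired_omics`) and `report`
#'   (data frame with columns step, n_features).
#' @export
filter_paired_omics <- function(data, threshold = 1,
                                min_samples = ceiling(n_samples(data) / 3)) {
  steps <- character(0); counts <- integer(0)
  note <- function(step, d) {
    steps <<- c(steps, step); counts <<- c(counts, n_features(d))
  }
  note("input", data)
  data <- filter_complete_pairs(data)
  note("complete_pairs", data)
  data <- filter_min_expression(data, threshold, min_samples)
  note("min_expression", data)
  data <- subset_features(data, good_features(data))
  note("good_features", data)
  list(data = data,
       report = data.frame(step = steps, n_features = counts))
}

#' Read one omics layer from TSV
#'
#' Expected dialect: tab-separated, first column feature identifiers,
#' header row of sample identifiers, `NA` for missing values.
#'
#' @param path TSV file path.
#' @return numeric features x samples matrix with dimnames.
#' @export
read_omics_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write one omics layer as TSV
#'
#' @param m features x samples matrix with dimnames.
#' @param path output path.
#' @param id_column name of the leading identifier column.
#' @export
write_omics_tsv <- function(m, path, id_column = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a paired data set from two layer TSVs
#'
#' @param transcript_path,protein_path TSV files in the dialect of
#'   [read_omics_tsv()].
#' @return a `paired_omics`.
#' @export
read_paired_omics <- function(transcript_path, protein_path) {
  paired_omics(read_omics_tsv(transcript_path), read_omics_tsv(protein_path))
}

#' Write a paired data set as two layer TSVs
#'
#' @param data a `paired_omics`.
#' @param transcript_path,protein_path output paths.
#' @export
write_paired_omics <- function(data, transcript_path, protein_path) {
  write_omics_tsv(data$transcript, transcript_path)
  write_omics_tsv(data$protein, protein_path)
  invisible(data)
}
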