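#' Construct a validated count matrix object
#'
#' The container the pipeline starts from: a genes x samples matrix of
#' non-negative integer read counts plus per-sample condition/replicate
#' metadata and optional per-gene effective lengths (used by TPM).
#' Modelled on the list-based expression containers of the count-based
#' differential-expression ecosystem.
#'
#' @param counts Integer-valued matrix, genes in rows, samples in
#'   columns; dimnames required (gene ids, sample ids), both unique.
#' @param sample_meta data.frame with columns \code{sample_id},
#'   \code{condition} (one of \code{LL}, \code{HH}, \code{L2H},
#'   \code{H2L}) and \code{replicate}; one row per column of
#'   \code{counts}, in any order.
#' @param effective_lengths Optional named numeric vector of per-gene
#'   effective lengths in nucleotides (> 0). Defaults to 1000 nt for
#'   every gene, which makes TPM proportional to counts.
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts}, \code{sample_meta} (ordered as the columns, with the
#'   condition fields of [condition_info()] merged in) and
#'   \code{effective_lengths}.
#' @export
count_matrix <- function(counts, sample_meta, effective_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("invalid count (negative or non-integer) at gene '",
         rownames(counts)[bad[1L, 1L]], "', sample '",
         colnames(counts)[bad[1L, 2L]], "'")
  }
  storage.mode(counts) <- "double"

  stopifnot(is.data.frame(sample_meta))
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(sample_meta))
  if (length(miss) > 0L)
    stop("sample_meta lacks column(s): ", paste(miss, collapse = ", "))
  if (!setequal(sample_meta$sample_id, colnames(counts)))
    stop("sample_meta sample ids do not match count matrix columns")
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  info <- condition_info(as.character(sample_meta$condition))
  sample_meta <- data.frame(
    sample_id     = sample_meta$sample_id,
    condition     = as.character(sample_meta$condition),
    replicate     = as.integer(sample_meta$replicate),
    glucose_level = info$glucose_level,
    is_shifted    = info$is_shifted,
    target_level  = info$target_level,
    stringsAsFactors = FALSE
  )
  rownames(sample_meta) <- NULL

  if (is.null(effective_lengths)) {
    effective_lengths <- stats::setNames(rep(1000, nrow(counts)), rownames(counts))
  } else {
    if (is.null(names(effective_lengths)))
      effective_lengths <- stats::setNames(effective_lengths, rownames(counts))
    effective_lengths <- effective_lengths[rownames(counts)]
    if (any(!is.finite(effective_lengths) | effective_lengths <= 0))
      stop("effective lengths must be positive and cover every gene")
  }

  structure(list(counts = counts, sample_meta = sample_meta,
                 effective_lengths = effective_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("conditions:",
      paste(sprintf("%s(%d)", names(table(x$sample_meta$condition)),
                    table(x$sample_meta$condition)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Samples (column indices) belonging to one condition label.
condition_samples <- function(mat, condition) {
  idx <- which(mat$sample_meta$condition == condition)
  if (length(idx) == 0L) stop("condition not present in matrix: ", condition)
  idx
}

# Require >= min_rep replicates for each requested condition.
check_replicates <- function(mat, conditions, min_rep = 2L) {
  for (cond in conditions) {
    n <- length(condition_samples(mat, cond))
    if (n < min_rep)
      stop("condition ", cond, " has ", n, " replicate(s); >= ", min_rep,
           " required")
  }
  invisible(TRUE)
}
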