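#' Construct a validated metabolite intensity table
#'
#' Holds LC-MS single-ion intensities for compounds measured under two
#' steady-state glucose conditions (low, like LL; high, like HH), with
#' observed m/z and retention time per compound.
#'
#' @param compounds data.frame with columns \code{compound_id},
#'   \code{mz} (Da), \code{rt} (minutes) and optionally
#'   \code{annotation} (e.g. a KEGG compound id or name).
#' @param intensities Numeric matrix, compounds x samples, strictly
#'   positive; rownames = compound ids, colnames = sample ids.
#' @param sample_meta data.frame with columns \code{sample_id},
#'   \code{condition} (\code{"low"} or \code{"high"}) and
#'   \code{replicate}; >= 3 replicates per condition.
#' @return Object of class \code{metabolite_table}.
#' @export
metabolite_table <- function(compounds, intensities, sample_meta) {
  intensities <- as.matrix(intensities)
  if (anyDuplicated(compounds$compound_id))
    stop("duplicate compound ids")
  if (nrow(intensities) > 0L &&
      !identical(as.character(compounds$compound_id), rownames(intensities)))
    stop("intensity rownames must equal compounds$compound_id, in order")
  if (any(!is.finite(intensities) | intensities <= 0))
    stop("intensities must be positive and finite")
  if (!setequal(sample_meta$sample_id, colnames(intensities)))
    stop("sample_meta ids do not match intensity columns")
  sample_meta <- sample_meta[match(colnames(intensities),
                                   sample_meta$sample_id), , drop = FALSE]
  if (!all(sample_meta$condition %in% c("low", "high")))
    stop("metabolite conditions must be 'low' or 'high'")
  if (is.null(compounds$annotation)) compounds$annotation <- NA_character_
  rownames(sample_meta) <- NULL
  structure(list(compounds = compounds, intensities = intensities,
                 sample_meta = sample_meta),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("metabolite_table:", nrow(x$intensities), "compounds x",
      ncol(x$intensities), "samples\n")
  invisible(x)
}

#' Read a metabolite table from CSV
#'
#' Main CSV: columns \code{compound_id}, \code{mz}, \code{rt},
#' optionally \code{annotation}, then one intensity column per sample.
#' Metadata CSV: columns \code{sample_id}, \code{condition}
#' (\code{low}/\code{high}), \code{replicate}.
#'
#' @param path Path to the intensity CSV.
#' @param meta_path Path to the sample metadata CSV.
#' @return A [metabolite_table()].
#' @export
read_metabolite_table <- function(path, meta_path) {
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, comment.char = "#",
                          stringsAsFactors = FALSE)
  fixed <- intersect(c("compound_id", "mz", "rt", "annotation"), names(tab))
  ints <- as.matrix(tab[, setdiff(names(tab), fixed), drop = FALSE])
  rownames(ints) <- as.character(tab$compound_id)
  metabolite_table(tab[, fixed, drop = FALSE], ints, meta)
}

#' Write a metabolite table to CSV (plus metadata CSV)
#' @param table A \code{metabolite_table}.
#' @param path Intensity CSV path.
#' @param meta_path Metadata CSV path.
#' @export
write_metabolite_table <- function(table, path, meta_path) {
  out <- cbind(table$compounds, as.data.frame(table$intensities))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(table$sample_meta, meta_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(path, meta_path))
}
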