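#' Read a count matrix and its sample metadata from TSV files
#'
#' Count file: tab-separated, UTF-8, lines starting with '#' ignored;
#' first column gene id, remaining columns one per sample. Metadata
#' file: tab-separated with columns \code{sample_id}, \code{condition},
#' \code{replicate}.
#'
#' @param path Path to the count TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @param lengths_path Optional TSV with columns \code{gene_id},
#'   \code{effective_length}.
#' @return A [count_matrix()] object; row and column order of the input
#'   file is preserved.
#' @export
read_count_matrix <- function(path, meta_path, lengths_path = NULL) {
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("count table needs a gene id column plus samples")
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- as.character(tab[[1L]])
  meta <- utils::read.delim(meta_path, comment.char = "#",
                            stringsAsFactors = FALSE)
  lens <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.delim(lengths_path, comment.char = "#",
                            stringsAsFactors = FALSE)
    lens <- stats::setNames(lt$effective_length, lt$gene_id)
  }
  count_matrix(counts, meta, lens)
}

#' Read a pathway map in GMT dialect
#'
#' One pathway per line: id, tab, name, tab, member gene ids separated
#' by tabs. Duplicate members within one pathway are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A named list of class \code{pathway_map}; each element is a
#'   list with \code{name} and \code{members} (unique character vector),
#'   named by pathway id. An empty file yields an empty map.
#' @export
read_pathway_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT parse error at line ", i, ": expected >= 3 tab-separated ",
           "fields (id, name, members...), got ", length(fields))
    id <- fields[[1L]]
    if (!is.null(out[[id]])) stop("duplicate pathway id: ", id)
    out[[id]] <- list(name = fields[[2L]],
                      members = unique(fields[-(1:2)]))
  }
  structure(out, class = "pathway_map")
}

#' Write a pathway map in GMT dialect
#' @param map A \code{pathway_map}.
#' @param path Output path.
#' @export
write_pathway_map <- function(map, path) {
  lines <- vapply(names(map), function(id) {
    paste(c(id, map[[id]]$name, map[[id]]$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns \code{gene_id}, \code{product}, \code{ec_numbers}
#' (semicolon-separated, may be empty), \code{pathway_ids}
#' (semicolon-separated, may be empty) and optionally
#' \code{isoform_group}.
#'
#' @param path Path to the annotation TSV.
#' @return data.frame with unique \code{gene_id} rows; the list-columns
#'   \code{ec_numbers} and \code{pathway_ids} hold character vectors.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id in annotation: ",
         tab$gene_id[duplicated(tab$gene_id)][1L])
  split_field <- function(x) {
    lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
           function(v) v[nzchar(v)])
  }
  tab$ec_numbers <- split_field(tab$ec_numbers)
  tab$pathway_ids <- split_field(tab$pathway_ids)
  if (is.null(tab$isoform_group)) tab$isoform_group <- NA_character_
  tab
}

#' Write a result table as TSV plus a full-precision JSON sidecar
#'
#' The TSV renders floating-point columns with 6 significant digits and
#' is meant for human inspection; the JSON sidecar (same path with
#' \code{.json} appended) carries full-precision values so downstream
#' numeric comparisons never depend on TSV rounding.
#'
#' @param records A data.frame of homogeneous records.
#' @param path Output TSV path.
#' @return Invisibly, the two paths written.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  fmt <- records
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- signif(fmt[[j]], 6)
    if (is.list(fmt[[j]]))
      fmt[[j]] <- vapply(fmt[[j]], paste, character(1), collapse = ";")
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  json_path <- paste0(path, ".json")
  jsonlite::write_json(records, json_path, digits = NA, na = "null")
  invisible(c(tsv = path, json = json_path))
}

#' Read back the JSON sidecar of a written result table
#' @param path The TSV path passed to [write_results_table()].
#' @return data.frame with full-precision values.
#' @export
read_results_json <- function(path) {
  jsonlite::fromJSON(paste0(path, ".json"))
}
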