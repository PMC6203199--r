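#' Ordered catalog of annotation columns
#'
#' An annotation schema fixes the layout of the binary annotation vector:
#' one column per (mark, cell type) pair plus global (non-cell-type-specific)
#' tracks such as conservation calls, an aggregated chromatin-state DHS call
#' and an aggregated chromatin-interaction call. The ordering is fixed and
#' persisted; every annotation matrix, background model and weight vector in
#' the package is laid out against a schema.
#'
#' @param annotation_id unique column identifiers, in canonical order.
#' @param mark assay or track type per column (e.g. "H3K27ac", "DNase",
#'   "GERP").
#' @param cell_type cell type per column, or `"global"` for tracks that are
#'   not cell-type-specific.
#' @param group tissue-group label per column (used for heatmap aggregation;
#'   defaults to the cell type).
#' @return an object of class `annotation_schema`: a data.frame with columns
#'   `annotation_id`, `mark`, `cell_type`, `group`.
#' @export
annotation_schema <- function(annotation_id, mark, cell_type,
                              group = cell_type) {
  annotation_id <- as.character(annotation_id)
  if (anyDuplicated(annotation_id)) {
    stop("annotation_schema: annotation_ids must be unique")
  }
  n <- length(annotation_id)
  mark <- rep_len(as.character(mark), n)
  cell_type <- rep_len(as.character(cell_type), n)
  group <- rep_len(as.character(group), n)
  s <- data.frame(annotation_id = annotation_id, mark = mark,
                  cell_type = cell_type, group = group,
                  stringsAsFactors = FALSE)
  class(s) <- c("annotation_schema", "data.frame")
  s
}

#' Number of annotation columns in a schema
#' @param schema an [annotation_schema].
#' @return integer column count.
#' @export
n_columns <- function(schema) nrow(schema)

#' Reference epigenome annotation layout
#'
#' Builds the full-scale layout used for genome-wide scoring: five chromatin
#' marks (H3K4me1, H3K4me3, H3K27ac, H3K9ac, DNase) for each reference
#' epigenome, plus four global columns: two conservation calls (GERP, SiPhy),
#' one aggregated chromatin-state DHS call and one aggregated
#' chromatin-interaction call. With the default 127 epigenomes this yields
#' 639 columns.
#'
#' @param cell_types character vector of epigenome/cell-type identifiers
#'   (default `E001`..`E127`).
#' @param marks chromatin marks assayed per cell type.
#' @param groups optional tissue-group label per cell type.
#' @return an [annotation_schema].
#' @export
epigenome_schema <- function(cell_types = sprintf("E%03d", 1:127),
                             marks = c("H3K4me1", "H3K4me3", "H3K27ac",
                                       "H3K9ac", "DNase"),
                             groups = cell_types) {
  groups <- rep_len(groups, length(cell_types))
  ct <- rep(cell_types, each = length(marks))
  gp <- rep(groups, each = length(marks))
  mk <- rep(marks, times = length(cell_types))
  ids <- paste(mk, ct, sep = ".")
  global_ids <- c("GERP", "SiPhy", "ChromHMM_DHS", "interaction")
  annotation_schema(
    annotation_id = c(ids, global_ids),
    mark = c(mk, "GERP", "SiPhy", "ChromHMM_DHS", "interaction"),
    cell_type = c(ct, rep("global", 4)),
    group = c(gp, rep("global", 4))
  )
}

#' Write / read a schema as TSV
#'
#' The persisted form is a 4-column tab-separated table
#' (annotation_id, mark, cell_type, group) in canonical order.
#'
#' @param schema an [annotation_schema].
#' @param path file path.
#' @return `read_schema` returns an [annotation_schema];
#'   `write_schema` returns `path` invisibly.
#' @export
write_schema <- function(schema, path) {
  utils::write.table(as.data.frame(schema), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, colClasses = "character")
  req <- c("annotation_id", "mark", "cell_type", "group")
  if (!all(req %in% names(d))) {
    stop("read_schema: file must have columns ", paste(req, collapse = ", "))
  }
  annotation_schema(d$annotation_id, d$mark, d$cell_type, d$group)
}

#' Hash of an annotation layout
#'
#' Every output file of a scoring run carries this hash so that score tables,
#' background models and weight vectors can be checked for layout agreement.
#'
#' @param schema an [annotation_schema].
#' @return character md5 digest of the ordered column catalog.
#' @export
schema_hash <- function(schema) {
  hash_string(paste(schema$annotation_id, schema$mark, schema$cell_type,
                    sep = "\t", collapse = "\n"))
}
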