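# Background-variant construction (filter cascade) and conversion of raw
# scores to empirical p-values.

#' Construct the background variant set by stepwise filtering
#'
#' Starting from a candidate list of common variants, removes in order:
#' (1) variants with a ClinVar-style status of Pathogenic, Likely pathogenic
#' or Uncertain significance; (2) variants present in a GWAS-catalog-style
#' table; (3) variants overlapping enhancer intervals; (4) variants with
#' allele frequency <= 0.05 in *any* provided continental ancestry column, or
#' with missing allele frequency. Per-step removal counts are logged.
#'
#' @param candidates variant table ([variant_table()]).
#' @param clinvar optional data.frame with columns `id`,
#'   `clinical_significance` (or path to such a TSV).
#' @param gwas_catalog optional data.frame with column `id` (or TSV path).
#' @param enhancers optional `GRanges` of enhancer intervals or a BED path.
#' @param af optional data.frame with column `id` plus one or more continental
#'   allele-frequency columns (e.g. `AFR`, `AMR`, `ASN`, `EUR`), or TSV path.
#' @param af_threshold frequency cutoff (default 0.05): candidates at or
#'   below it in any ancestry are removed.
#' @param chrom_style chromosome-name dialect for BED enhancers.
#' @return object of class `background_set`: list with `variants` (the
#'   survivors), `filter_log` (data.frame: step, n_before, n_removed,
#'   n_after), `n_missing_af`.
#' @export
construct_background <- function(candidates, clinvar = NULL,
                                 gwas_catalog = NULL, enhancers = NULL,
                                 af = NULL, af_threshold = 0.05,
                                 chrom_style = "strip") {
  read_tsv <- function(x) {
    if (is.character(x) && length(x) == 1L) {
      utils::read.table(x, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    } else x
  }
  clinvar <- read_tsv(clinvar)
  gwas_catalog <- read_tsv(gwas_catalog)
  af <- read_tsv(af)
  if (is.character(enhancers)) {
    enhancers <- load_peak_track(enhancers, "enhancers", chrom_style)
  }
  if (nrow(candidates) == 0L) {
    warning("construct_background: empty candidate list")
  }
  log <- data.frame(step = character(0), n_before = integer(0),
                    n_removed = integer(0), n_after = integer(0))
  note <- function(step, before, after) {
    rbind(log, data.frame(step = step, n_before = nrow(before),
                          n_removed = nrow(before) - nrow(after),
                          n_after = nrow(after)))
  }
  cur <- candidates
  if (!is.null(clinvar)) {
    bad_status <- c("Pathogenic", "Likely pathogenic", "Uncertain significance")
    bad_ids <- clinvar$id[clinvar$clinical_significance %in% bad_status]
    nxt <- cur[!(cur$id %in% bad_ids), , drop = FALSE]
    log <- note("clinvar", cur, nxt); cur <- nxt
  }
  if (!is.null(gwas_catalog)) {
    nxt <- cur[!(cur$id %in% gwas_catalog$id), , drop = FALSE]
    log <- note("gwas_catalog", cur, nxt); cur <- nxt
  }
  if (!is.null(enhancers)) {
    hit <- GenomicRanges::countOverlaps(variants_granges(cur), enhancers,
                                        ignore.strand = TRUE) > 0L
    nxt <- cur[!hit, , drop = FALSE]
    log <- note("enhancer", cur, nxt); cur <- nxt
  }
  n_missing_af <- 0L
  if (!is.null(af)) {
    af_cols <- setdiff(names(af), "id")
    m <- match(cur$id, af$id)
    vals <- as.matrix(af[m, af_cols, drop = FALSE])
    missing_af <- is.na(m) | rowSums(is.na(vals)) > 0L
    n_missing_af <- sum(missing_af)
    low <- !missing_af & rowSums(vals <= af_threshold, na.rm = TRUE) > 0L
    nxt <- cur[!(missing_af | low), , drop = FALSE]
    log <- note("allele_frequency", cur, nxt); cur <- nxt
  }
  structure(list(variants = cur, filter_log = log,
                 n_missing_af = n_missing_af),
            class = "background_set")
}

#' @export
print.background_set <- function(x, ...) {
  cat(sprintf("background_set: %d variants after filtering\n", nrow(x$variants)))
  print(x$filter_log, row.names = FALSE)
  invisible(x)
}

#' Score variants against per-class background distributions
#'
#' Each variant is scored with its own class's background model and compared
#' with the raw scores of background variants of the same class under the
#' *same* weight vector (the background is re-scored for every new W, which
#' is what makes weighted and unweighted p-values comparable). Excluded-class
#' variants are reported unscored. Variants with an undefined whitened angle
#' receive empirical p = 1 and are flagged.
#'
#' @param mat [annotation_matrix()] of query variants.
#' @param models a single [background_model()] or a named list of models by
#'   class (`intronic`, `intergenic`, `pooled`). A class without its own
#'   model falls back to `pooled` when present.
#' @param background [annotation_matrix()] of background variants (class
#'   labels used when per-class models are given).
#' @param W optional weights (see [whiten()]).
#' @param weight_source provenance label recorded in the output (default
#'   inferred: `"unweighted"` when `W` is NULL or a plain vector,
#'   otherwise the weight vector's own source).
#' @return a score table: data.frame with `chrom`, `pos`, `id`, `class`,
#'   `raw_score`, `empirical_p`, `weight_source`, `undefined`.
#' @export
score_variants <- function(mat, models, background, W = NULL,
                           weight_source = NULL) {
  if (inherits(models, "background_model")) {
    models <- stats::setNames(list(models), models$variant_class)
  }
  if (is.null(weight_source)) {
    weight_source <- if (inherits(W, "weight_vector")) W$source
                     else if (is.null(W)) "unweighted" else "custom"
  }
  cls <- mat$variants$variant_class
  cls[is.na(cls)] <- "pooled"
  out <- data.frame(chrom = mat$variants$chrom, pos = mat$variants$pos,
                    id = mat$variants$id, class = cls,
                    raw_score = NA_real_, empirical_p = NA_real_,
                    weight_source = weight_source, undefined = FALSE,
                    stringsAsFactors = FALSE)
  for (cl in setdiff(unique(cls), "excluded")) {
    model <- models[[cl]] %||% models[["pooled"]]
    if (is.null(model)) {
      stop("score_variants: no background model for class '", cl, "'")
    }
    bg_class <- if (!is.null(models[[cl]])) cl else "pooled"
    bg_rows <- class_rows(background, bg_class)
    if (length(bg_rows) == 0L) {
      stop("score_variants: no background variants for class '", cl, "'")
    }
    bg_scores <- score_matrix(background$values[bg_rows, , drop = FALSE],
                              model, W)
    bg_raw <- bg_scores$raw_score[!bg_scores$undefined]
    if (length(bg_raw) == 0L) {
      stop("score_variants: background scores all undefined for class '", cl, "'")
    }
    rows <- which(cls == cl)
    sc <- score_matrix(mat$values[rows, , drop = FALSE], model, W)
    out$raw_score[rows] <- sc$raw_score
    out$undefined[rows] <- sc$undefined
    out$empirical_p[rows] <- ifelse(sc$undefined, 1,
                                    empirical_pvalue(sc$raw_score, bg_raw,
                                                     tail = "left"))
  }
  out
}

#' Write a score table as TSV
#'
#' A `# schema_hash:` header line records the annotation layout used.
#'
#' @param scores a score table from [score_variants()].
#' @param path output file.
#' @param schema_hash optional layout hash to record.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, schema_hash = NA_character_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# schema_hash: %s", schema_hash), con)
  utils::write.table(scores, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
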