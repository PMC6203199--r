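# Reading variants and interval tracks, building the binary annotation
# matrix, and classifying variants by genomic context.

#' Load a BED/narrowPeak peak track
#'
#' Reads a >=3-column BED (or narrowPeak, whose first three columns are BED)
#' into a `GRanges`. BED coordinates are 0-based half-open; the returned
#' ranges use the usual 1-based closed convention (`[start+1, end]`), so a
#' 1-based variant position overlaps the track iff its 0-based coordinate
#' falls inside the original half-open interval.
#'
#' @param path BED/narrowPeak file path.
#' @param track_id identifier stored with the track.
#' @param chrom_style chromosome-name dialect passed to [normalize_chrom()].
#' @return a `GRanges` with metadata columns absent; the track id is kept in
#'   `metadata()`. An empty file yields an empty `GRanges`.
#' @export
load_peak_track <- function(path, track_id = basename(path),
                            chrom_style = "strip") {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$track_id <- track_id
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- lineno[which(nf < 3L)[1]]
    stop(sprintf("load_peak_track: malformed line %d in %s (need >= 3 tab-separated fields)",
                 bad, path))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0)) {
    bad <- lineno[which(is.na(start0) | is.na(end0))[1]]
    stop(sprintf("load_peak_track: malformed line %d in %s (non-integer coordinates)",
                 bad, path))
  }
  if (any(start0 >= end0)) {
    bad <- lineno[which(start0 >= end0)[1]]
    stop(sprintf("load_peak_track: rejected record at line %d in %s (start >= end)",
                 bad, path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(chrom, chrom_style),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
  )
  S4Vectors::metadata(gr)$track_id <- track_id
  gr
}

#' Read variant positions
#'
#' Accepts a VCF (only CHROM/POS/ID are used) or a 3-column tab-separated
#' file (chrom, pos, id). Positions are 1-based.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param chrom_style chromosome-name dialect.
#' @return data.frame with columns `chrom`, `pos`, `id`, `variant_class`
#'   (NA until [classify_variants()]), `tss_distance` (NA).
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          chrom_style = "strip") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    d <- data.frame(chrom = vcfR::getCHROM(v),
                    pos = as.integer(vcfR::getPOS(v)),
                    id = vcfR::getID(v),
                    stringsAsFactors = FALSE)
  } else {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "pos", "id"),
                           colClasses = c("character", "integer", "character"))
  }
  variant_table(d$chrom, d$pos, d$id, chrom_style = chrom_style)
}

#' Assemble a variant table
#'
#' @param chrom,pos,id vectors describing the variants (pos is 1-based; for
#'   indels the leftmost position is used).
#' @param variant_class optional class per variant
#'   (`intronic`/`intergenic`/`excluded`).
#' @param chrom_style chromosome-name dialect.
#' @return data.frame as in [read_variants()].
#' @export
variant_table <- function(chrom, pos, id = NULL, variant_class = NA_character_,
                          chrom_style = "strip") {
  pos <- as.integer(pos)
  if (any(pos < 1L, na.rm = TRUE)) stop("variant_table: positions must be >= 1")
  n <- length(pos)
  if (is.null(id)) id <- sprintf("v%05d", seq_len(n))
  data.frame(chrom = normalize_chrom(chrom, chrom_style),
             pos = pos,
             id = as.character(id),
             variant_class = rep_len(as.character(variant_class), n),
             tss_distance = rep_len(NA_integer_, n),
             stringsAsFactors = FALSE)
}

variants_granges <- function(variants) {
  GenomicRanges::GRanges(seqnames = variants$chrom,
                         ranges = IRanges::IRanges(start = variants$pos,
                                                   width = 1L))
}

#' Construct an annotation matrix object
#'
#' @param variants a variant table (see [variant_table()]).
#' @param values numeric/integer matrix of 0/1/NA entries, variants in rows,
#'   schema columns in columns.
#' @param schema the [annotation_schema] describing the columns.
#' @return object of class `annotation_matrix` (list with elements
#'   `variants`, `values`, `schema`).
#' @export
annotation_matrix <- function(variants, values, schema) {
  values <- as.matrix(values)
  if (ncol(values) != n_columns(schema)) {
    stop("annotation_matrix: values must have one column per schema entry")
  }
  if (nrow(values) != nrow(variants)) {
    stop("annotation_matrix: one row per variant required")
  }
  bad <- values[!is.na(values)]
  if (length(bad) && !all(bad %in% c(0, 1))) {
    stop("annotation_matrix: entries must be 0, 1 or NA")
  }
  dimnames(values) <- list(variants$id, schema$annotation_id)
  structure(list(variants = variants, values = values, schema = schema),
            class = "annotation_matrix")
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("annotation_matrix: %d variants x %d annotations (%d missing entries)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  cls <- table(x$variants$variant_class, useNA = "ifany")
  cat("classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.annotation_matrix <- function(x) dim(x$values)

#' Build the binary annotation matrix for a set of variants
#'
#' Each entry is 1 iff the variant position overlaps at least one interval of
#' the column's track, 0 otherwise, and NA (missing) when no track is
#' available for the column. A schema column mapped to a *list* of tracks is
#' aggregated by union before overlap (used for chromatin-interaction data
#' pooled across cell types).
#'
#' @param variants variant table ([variant_table()]).
#' @param tracks named list mapping `annotation_id` to a `GRanges` (from
#'   [load_peak_track()]) or to a list of `GRanges` to be unioned. Schema
#'   columns absent from `tracks` are recorded as missing for all variants.
#' @param schema the [annotation_schema].
#' @return an [annotation_matrix()].
#' @export
build_annotation_matrix <- function(variants, tracks, schema) {
  unknown <- setdiff(names(tracks), schema$annotation_id)
  if (length(unknown)) {
    stop("build_annotation_matrix: tracks not in schema: ",
         paste(unknown, collapse = ", "))
  }
  vgr <- variants_granges(variants)
  d <- n_columns(schema)
  values <- matrix(NA_integer_, nrow = nrow(variants), ncol = d)
  track_chroms <- character(0)
  for (j in seq_len(d)) {
    id <- schema$annotation_id[j]
    tr <- tracks[[id]]
    if (is.null(tr)) next
    if (is.list(tr)) tr <- Reduce(c, tr)        # aggregate, e.g. interaction data
    track_chroms <- union(track_chroms,
                          as.character(GenomeInfoDb::seqlevelsInUse(tr)))
    values[, j] <- as.integer(
      GenomicRanges::countOverlaps(vgr, tr, ignore.strand = TRUE) > 0L)
  }
  orphan <- !(variants$chrom %in% track_chroms)
  if (any(orphan) && length(track_chroms)) {
    warning(sprintf("build_annotation_matrix: %d variant(s) on chromosomes absent from all tracks (all-zero rows)",
                    sum(orphan)))
  }
  annotation_matrix(variants, values, schema)
}

#' Classify variants as intronic / intergenic / excluded
#'
#' A variant inside a transcript but outside all exons is intronic; outside
#' all transcripts it is intergenic; inside an exon (which includes UTRs in
#' standard gene models) it is excluded from scoring, since the score is
#' defined for noncoding variants only. Every variant is also annotated with
#' the distance to the nearest transcription start site.
#'
#' @param variants variant table.
#' @param gene_model path to a GFF3 or BED12 gene model, or a list with
#'   `GRanges` elements `transcripts`, `exons`, `tss`.
#' @param chrom_style chromosome-name dialect.
#' @return the variant table with `variant_class` and `tss_distance` filled.
#' @export
classify_variants <- function(variants, gene_model, chrom_style = "strip") {
  gm <- if (is.character(gene_model)) {
    read_gene_model(gene_model, chrom_style)
  } else {
    gene_model
  }
  if (length(gm$transcripts) == 0L) {
    stop("classify_variants: empty gene model, classification impossible")
  }
  vgr <- variants_granges(variants)
  in_tx <- GenomicRanges::countOverlaps(vgr, gm$transcripts,
                                        ignore.strand = TRUE) > 0L
  in_ex <- GenomicRanges::countOverlaps(vgr, gm$exons,
                                        ignore.strand = TRUE) > 0L
  variants$variant_class <- ifelse(in_ex, "excluded",
                                   ifelse(in_tx, "intronic", "intergenic"))
  tss_pos <- GenomicRanges::start(gm$tss)
  tss_chrom <- as.character(GenomicRanges::seqnames(gm$tss))
  variants$tss_distance <- vapply(seq_len(nrow(variants)), function(i) {
    same <- tss_chrom == variants$chrom[i]
    if (!any(same)) return(NA_integer_)
    as.integer(min(abs(tss_pos[same] - variants$pos[i])))
  }, integer(1))
  variants
}

#' Read a gene model from GFF3 or BED12
#'
#' Extracts transcript spans, exon spans and TSS positions. For GFF3,
#' transcripts are features of type `transcript`/`mRNA` (falling back to
#' `gene` when no transcript features exist) and exons are type `exon`. For
#' BED12 the thick line is the transcript and the blocks are exons. The TSS
#' is the 5' end of each transcript (strand-aware).
#'
#' @param path gene model file (`.gff3`/`.gff` or `.bed`).
#' @param chrom_style chromosome-name dialect.
#' @return list of `GRanges`: `transcripts`, `exons`, `tss`.
#' @export
read_gene_model <- function(path, chrom_style = "strip") {
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    g <- rtracklayer::import(path)
    types <- as.character(g$type)
    tx <- g[types %in% c("transcript", "mRNA")]
    if (length(tx) == 0L) tx <- g[types == "gene"]
    ex <- g[types == "exon"]
  } else {
    b <- rtracklayer::import(path, format = "BED")
    tx <- b
    ex <- if (!is.null(b$blocks)) {
      unlist(rtracklayer::blocks(b), use.names = FALSE)
    } else {
      b
    }
  }
  norm <- function(gr) {
    GenomeInfoDb::seqlevels(gr) <- normalize_chrom(GenomeInfoDb::seqlevels(gr),
                                                   chrom_style)
    gr
  }
  tx <- norm(tx); ex <- norm(ex)
  tss <- GenomicRanges::resize(tx, width = 1L, fix = "start")  # strand-aware 5' end
  list(transcripts = tx, exons = ex, tss = tss)
}
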