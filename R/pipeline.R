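# High-level pipeline commands and the command-line front end. Each command
# is a thin wrapper over the module functions, writes its outputs plus a
# resolved-config copy, and logs per-stage record counts.

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

read_tracks_manifest <- function(path, chrom_style = "strip") {
  man <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("annotation_id", "path") %in% names(man))) {
    stop("tracks manifest must have columns annotation_id, path")
  }
  base <- dirname(path)
  tracks <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p)) stop("track file not found: ", man$path[i])
    load_peak_track(p, man$annotation_id[i], chrom_style)
  })
  stats::setNames(tracks, man$annotation_id)
}

#' Build a background variant set from candidate variants and filter tables
#'
#' Runs the filter cascade ([construct_background()]) and writes the
#' surviving variants, the per-step filter log and a resolved-config copy to
#' `out_dir`.
#'
#' @param variants path to candidate variants (VCF or 3-column TSV).
#' @param clinvar,gwas_catalog,af paths to the filter tables (TSV); any may
#'   be `NULL` to skip that step.
#' @param enhancers path to an enhancer BED, or `NULL`.
#' @param out_dir output directory.
#' @param chrom_style chromosome-name dialect.
#' @param verbose log per-stage counts.
#' @return the `background_set`, invisibly.
#' @export
pines_build_background <- function(variants, clinvar = NULL,
                                   gwas_catalog = NULL, enhancers = NULL,
                                   af = NULL, out_dir = ".",
                                   chrom_style = "strip", verbose = TRUE) {
  for (f in c(variants, clinvar, gwas_catalog, enhancers, af)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cand <- read_variants(variants, chrom_style = chrom_style)
  log_stage(verbose, "candidates: %d", nrow(cand))
  bg <- construct_background(cand, clinvar, gwas_catalog, enhancers, af,
                             chrom_style = chrom_style)
  for (i in seq_len(nrow(bg$filter_log))) {
    log_stage(verbose, "filter %-16s removed %d -> %d left",
              bg$filter_log$step[i], bg$filter_log$n_removed[i],
              bg$filter_log$n_after[i])
  }
  utils::write.table(bg$variants, file.path(out_dir, "background_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bg$filter_log, file.path(out_dir, "filter_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(command = "build-background", variants = variants,
                        clinvar = clinvar, gwas_catalog = gwas_catalog,
                        enhancers = enhancers, af = af,
                        n_missing_af = bg$n_missing_af),
                   file.path(out_dir, "config.yaml"))
  invisible(bg)
}

# shared by score/weights commands: read variants + tracks, build matrix,
# classify when a gene model is given
assemble_matrix <- function(variants, tracks_manifest, gene_model = NULL,
                            chrom_style = "strip", verbose = TRUE) {
  v <- read_variants(variants, chrom_style = chrom_style)
  log_stage(verbose, "variants read: %d", nrow(v))
  tracks <- read_tracks_manifest(tracks_manifest, chrom_style)
  man <- utils::read.table(tracks_manifest, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  schema <- annotation_schema(
    man$annotation_id,
    mark = man$mark %||% man$annotation_id,
    cell_type = man$cell_type %||% "global",
    group = man$group %||% man$cell_type %||% "global")
  if (!is.null(gene_model)) {
    v <- classify_variants(v, gene_model, chrom_style)
    log_stage(verbose, "classified: %s",
              paste(names(table(v$variant_class)), table(v$variant_class),
                    sep = "=", collapse = ", "))
  } else {
    v$variant_class <- "intergenic"   # pooled handling downstream
  }
  build_annotation_matrix(v, tracks, schema)
}

#' Score variants end to end
#'
#' Reads query and background variants, annotates both against the track
#' manifest, optionally classifies them against a gene model (intronic and
#' intergenic variants then get separate background models), resolves the
#' weight vector (unweighted, manual constant on selected annotations, or a
#' precomputed weight table), scores, and writes the score table.
#'
#' @param variants path to query variants (VCF or TSV).
#' @param tracks_manifest TSV with columns `annotation_id`, `path` (and
#'   optionally `mark`, `cell_type`, `group`) defining the annotation layout.
#' @param background_variants path to background variants (VCF or TSV).
#' @param gene_model optional gene model (GFF3/BED12) for classification.
#' @param weights `NULL` (unweighted), a path to a weight TSV
#'   (`annotation_id`, `weight`), or a [weight_vector()].
#' @param select,constant manual weighting: annotation ids to up-weight and
#'   the weighting constant (used when `weights` is NULL and `select` given).
#' @param k background model rank.
#' @param out_dir output directory.
#' @param chrom_style chromosome-name dialect.
#' @param verbose log per-stage counts.
#' @return the score table, invisibly.
#' @export
pines_score_run <- function(variants, tracks_manifest, background_variants,
                            gene_model = NULL, weights = NULL,
                            select = NULL, constant = 4, k = 30,
                            out_dir = ".", chrom_style = "strip",
                            verbose = TRUE) {
  for (f in c(variants, tracks_manifest, background_variants, gene_model)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  qmat <- assemble_matrix(variants, tracks_manifest, gene_model,
                          chrom_style, verbose)
  bmat <- assemble_matrix(background_variants, tracks_manifest, gene_model,
                          chrom_style, verbose)
  W <- if (inherits(weights, "weight_vector")) {
    weights
  } else if (is.character(weights)) {
    wt <- utils::read.table(weights, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    m <- match(qmat$schema$annotation_id, wt$annotation_id)
    if (anyNA(m)) stop("weight table is missing annotation ids")
    weight_vector(wt$weight[m], source = "file", schema = qmat$schema)
  } else if (!is.null(select)) {
    manual_weights(qmat$schema, select, constant)
  } else {
    NULL
  }
  classes <- setdiff(unique(qmat$variants$variant_class), "excluded")
  models <- list()
  for (cl in classes) {
    n_cl <- length(class_rows(bmat, cl))
    models[[cl]] <- if (n_cl > k) {
      estimate_background_model(bmat, cl, k = min(k, ncol(bmat$values)))
    } else {
      estimate_background_model(bmat, "pooled",
                                k = min(k, ncol(bmat$values)))
    }
  }
  st <- score_variants(qmat, models, bmat, W = W)
  log_stage(verbose, "scored: %d variants (%d excluded)",
            sum(st$class != "excluded"), sum(st$class == "excluded"))
  write_score_table(st, file.path(out_dir, "scores.tsv"),
                    schema_hash = schema_hash(qmat$schema))
  yaml::write_yaml(list(command = "score", variants = variants,
                        tracks_manifest = tracks_manifest,
                        background_variants = background_variants,
                        gene_model = gene_model, k = k,
                        weight_source = unique(st$weight_source),
                        schema_hash = schema_hash(qmat$schema)),
                   file.path(out_dir, "config.yaml"))
  invisible(st)
}

#' Learn enrichment weights from lead SNPs, end to end
#'
#' Annotates lead SNPs and universe variants against the track manifest and
#' runs [enrichment_weights()]; writes the weight table.
#'
#' @param leads path to a lead-SNP TSV with columns `chrom`, `pos`, `id`,
#'   `af`.
#' @param universe path to universe variants (VCF or TSV).
#' @param universe_af path to an AF TSV (`id` plus a reference AF column
#'   named `af`, or the first non-id column is used).
#' @param tracks_manifest annotation layout (as in [pines_score_run()]).
#' @param n_draws,bin_width,weight_floor,seed see [enrichment_weights()].
#' @param out_dir output directory.
#' @param chrom_style chromosome-name dialect.
#' @param verbose log per-stage counts.
#' @return the [enrichment_weights()] result, invisibly.
#' @export
pines_weights_run <- function(leads, universe, universe_af, tracks_manifest,
                              n_draws = 1000, bin_width = 0.05,
                              weight_floor = 0.1, seed = NULL,
                              out_dir = ".", chrom_style = "strip",
                              verbose = TRUE) {
  for (f in c(leads, universe, universe_af, tracks_manifest)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lead_tab <- utils::read.table(leads, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  lv <- variant_table(lead_tab$chrom, lead_tab$pos, lead_tab$id,
                      chrom_style = chrom_style)
  tracks <- read_tracks_manifest(tracks_manifest, chrom_style)
  man <- utils::read.table(tracks_manifest, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  schema <- annotation_schema(man$annotation_id,
                              mark = man$mark %||% man$annotation_id,
                              cell_type = man$cell_type %||% "global")
  lmat <- build_annotation_matrix(lv, tracks, schema)
  uv <- read_variants(universe, chrom_style = chrom_style)
  umat <- build_annotation_matrix(uv, tracks, schema)
  af_tab <- utils::read.table(universe_af, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  af_col <- if ("af" %in% names(af_tab)) "af" else setdiff(names(af_tab), "id")[1]
  u_af <- af_tab[[af_col]][match(uv$id, af_tab$id)]
  ew <- enrichment_weights(lmat, lead_tab$af, umat, u_af,
                           n_draws = n_draws, bin_width = bin_width,
                           weight_floor = weight_floor, seed = seed)
  log_stage(verbose, "weights: %d annotations, max weight %.3f",
            nrow(ew$result), max(ew$result$weight))
  write_weight_table(ew, file.path(out_dir, "weights.tsv"))
  yaml::write_yaml(list(command = "weights", leads = leads,
                        universe = universe, n_draws = n_draws,
                        bin_width = bin_width, weight_floor = weight_floor,
                        seed = seed, schema_hash = schema_hash(schema)),
                   file.path(out_dir, "config.yaml"))
  invisible(ew)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `build-background`, `score`, `weights` and
#' `simulate`. Installed as a thin Rscript front end under
#' `system.file("cli", "pines.R", package = "pines")`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status (0 on success), invisibly.
#' @export
pines_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: pines.R <build-background|score|weights|simulate> [options]"
  if (length(args) < 1L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  o <- function(...) optparse::make_option(...)
  common <- list(
    o("--out-dir", type = "character", default = ".", dest = "out_dir"),
    o("--chrom-style", type = "character", default = "strip",
      dest = "chrom_style"))
  if (cmd == "build-background") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = c(list(
      o("--variants", type = "character"),
      o("--clinvar", type = "character", default = NULL),
      o("--gwas-catalog", type = "character", default = NULL,
        dest = "gwas_catalog"),
      o("--enhancers", type = "character", default = NULL),
      o("--af", type = "character", default = NULL)), common)), args = rest)
    pines_build_background(opts$variants, opts$clinvar, opts$gwas_catalog,
                           opts$enhancers, opts$af, opts$out_dir,
                           opts$chrom_style)
  } else if (cmd == "score") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = c(list(
      o("--variants", type = "character"),
      o("--tracks", type = "character"),
      o("--background", type = "character"),
      o("--gene-model", type = "character", default = NULL,
        dest = "gene_model"),
      o("--weights", type = "character", default = NULL),
      o("--select", type = "character", default = NULL,
        help = "comma-separated annotation ids to up-weight"),
      o("--weight-constant", type = "double", default = 4,
        dest = "constant"),
      o("--k", type = "integer", default = 30)), common)), args = rest)
    select <- if (!is.null(opts$select)) strsplit(opts$select, ",")[[1]]
    pines_score_run(opts$variants, opts$tracks, opts$background,
                    opts$gene_model, opts$weights, select, opts$constant,
                    opts$k, opts$out_dir, opts$chrom_style)
  } else if (cmd == "weights") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = c(list(
      o("--leads", type = "character"),
      o("--universe", type = "character"),
      o("--universe-af", type = "character", dest = "universe_af"),
      o("--tracks", type = "character"),
      o("--n-draws", type = "integer", default = 1000, dest = "n_draws"),
      o("--af-bin-width", type = "double", default = 0.05,
        dest = "bin_width"),
      o("--weight-floor", type = "double", default = 0.1,
        dest = "weight_floor"),
      o("--seed", type = "integer", default = 1)), common)), args = rest)
    pines_weights_run(opts$leads, opts$universe, opts$universe_af,
                      opts$tracks, opts$n_draws, opts$bin_width,
                      opts$weight_floor, opts$seed, opts$out_dir,
                      opts$chrom_style)
  } else if (cmd == "simulate") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = c(list(
      o("--seed", type = "integer", default = 1)), common)), args = rest)
    generate_fixture_tracks(opts$out_dir, seed = opts$seed)
    message("fixture bundle written to ", opts$out_dir)
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
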