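# Simulators for binary annotation matrices (independent, block-correlated
# and general correlated via a Gaussian copula) and toy genomic fixture
# bundles, so the whole pipeline is testable without external downloads.

#' Synthetic annotation schema
#'
#' @param n_annotations number of columns.
#' @param prefix id prefix.
#' @return an [annotation_schema] with one simulated cell type per column.
#' @export
synthetic_schema <- function(n_annotations, prefix = "A") {
  ids <- sprintf("%s%03d", prefix, seq_len(n_annotations))
  annotation_schema(ids, mark = "sim",
                    cell_type = sprintf("ct%03d", seq_len(n_annotations)))
}

simulated_variants <- function(n, prefix = "s") {
  variant_table(chrom = rep("1", n), pos = seq_len(n),
                id = sprintf("%s%05d", prefix, seq_len(n)),
                variant_class = "intergenic")
}

#' Simulate background plus cell-type-specific variants
#'
#' Background variants draw every annotation independently from
#' Bernoulli(`p_background`). Cell-type-specific variants draw a designated
#' set of "hot" annotations from Bernoulli(`p_hot`) and the remaining
#' annotations from Bernoulli(`p_cold`). Defaults reproduce the standard
#' simulation design: 5000 background and 100 specific variants over 100
#' annotations with 10 hot annotations and probabilities 0.3 / 0.9 / 0.1.
#'
#' @param n_background,n_specific row counts.
#' @param n_annotations,n_hot column counts (hot annotations are the first
#'   `n_hot` columns after a random permutation draw; see `hot_ids` in the
#'   result).
#' @param p_background,p_hot,p_cold Bernoulli probabilities, all in (0,1).
#' @param seed RNG seed (mandatory: simulations are reproducible by design).
#' @return list with `matrix` (an [annotation_matrix()], background rows
#'   first), `labels` (`"background"`/`"specific"` per row) and `hot_ids`
#'   (annotation ids of the hot columns).
#' @export
simulate_celltype_specific <- function(n_background = 5000, n_specific = 100,
                                       n_annotations = 100, n_hot = 10,
                                       p_background = 0.3, p_hot = 0.9,
                                       p_cold = 0.1, seed) {
  probs <- c(p_background, p_hot, p_cold)
  if (any(probs <= 0 | probs >= 1)) {
    stop("simulate_celltype_specific: probabilities must lie in (0, 1)")
  }
  set.seed(seed)
  schema <- synthetic_schema(n_annotations)
  hot <- sort(sample.int(n_annotations, n_hot))
  bg <- matrix(stats::rbinom(n_background * n_annotations, 1, p_background),
               nrow = n_background)
  sp <- matrix(stats::rbinom(n_specific * n_annotations, 1, p_cold),
               nrow = n_specific)
  sp[, hot] <- stats::rbinom(n_specific * n_hot, 1, p_hot)
  values <- rbind(bg, sp)
  labels <- rep(c("background", "specific"), c(n_background, n_specific))
  mat <- annotation_matrix(simulated_variants(nrow(values)), values, schema)
  list(matrix = mat, labels = labels,
       hot_ids = schema$annotation_id[hot])
}

# latent exchangeable Gaussian correlation that yields a target *binary*
# (phi) correlation after thresholding both margins at Bernoulli(p)
calibrate_latent_rho <- function(target_phi, p) {
  if (target_phi == 0) return(0)
  t <- stats::qnorm(1 - p)
  phi_of <- function(r) {
    p11 <- mvtnorm::pmvnorm(lower = c(t, t), upper = c(Inf, Inf),
                            corr = matrix(c(1, r, r, 1), 2))[1]
    (p11 - p^2) / (p * (1 - p))
  }
  hi <- 0.9999
  if (target_phi < 0 || target_phi >= phi_of(hi)) {
    stop(sprintf("calibrate_latent_rho: binary correlation %.3f infeasible for Bernoulli(%.3f) margins",
                 target_phi, p))
  }
  stats::uniroot(function(r) phi_of(r) - target_phi, c(0, hi),
                 tol = 1e-6)$root
}

#' Simulate block-correlated binary annotations
#'
#' Binary annotations organized in blocks: annotations within a block are
#' positively correlated, annotations in different blocks are independent.
#' Correlated binaries are produced by a Gaussian copula with exchangeable
#' within-block latent correlation, thresholded at the Bernoulli quantile;
#' the latent correlation is calibrated so that the realized *binary*
#' correlation matches `within_block_correlation`.
#'
#' @param n_variants number of rows (default 10000).
#' @param block_sizes annotation count per block (default ten blocks of 10).
#' @param within_block_correlation target pairwise binary correlation within
#'   a block, in `[0, 1)` (default 0.7).
#' @param p marginal Bernoulli probability per annotation (default 0.3).
#' @param seed RNG seed (mandatory).
#' @return an [annotation_matrix()] with attribute `block` (block index per
#'   column).
#' @export
simulate_blocks <- function(n_variants = 10000, block_sizes = rep(10, 10),
                            within_block_correlation = 0.7, p = 0.3, seed) {
  if (p <= 0 || p >= 1) stop("simulate_blocks: p must lie in (0, 1)")
  if (within_block_correlation < 0 || within_block_correlation >= 1) {
    stop("simulate_blocks: within_block_correlation must lie in [0, 1)")
  }
  set.seed(seed)
  rl <- calibrate_latent_rho(within_block_correlation, p)
  d <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  t <- stats::qnorm(1 - p)
  Z <- matrix(stats::rnorm(n_variants * d), nrow = n_variants)
  if (rl > 0) {
    f <- matrix(stats::rnorm(n_variants * length(block_sizes)),
                nrow = n_variants)
    Z <- sqrt(rl) * f[, block] + sqrt(1 - rl) * Z
  }
  values <- matrix(as.integer(Z > t), nrow = n_variants)
  mat <- annotation_matrix(simulated_variants(n_variants),
                           values, synthetic_schema(d))
  attr(mat, "block") <- block
  mat
}

#' Random positive-definite correlation matrix
#'
#' Built from a random factor model with one dominant positive factor (so
#' that annotations are, on the whole, positively correlated, as epigenetic
#' annotations are) plus minor factors, normalized to unit diagonal.
#'
#' @param d dimension.
#' @param n_minor_factors number of minor factors (default 2).
#' @param seed RNG seed (mandatory).
#' @return d x d correlation matrix (positive definite).
#' @export
random_correlation_matrix <- function(d, n_minor_factors = 2, seed) {
  set.seed(seed)
  L <- cbind(stats::runif(d, 0.4, 0.8),
             matrix(stats::rnorm(d * n_minor_factors, 0, 0.25), nrow = d))
  ss <- rowSums(L^2)
  over <- ss > 0.95
  if (any(over)) L[over, ] <- L[over, ] * sqrt(0.95 / ss[over])
  Sigma <- tcrossprod(L)
  diag(Sigma) <- 1
  Sigma
}

#' Simulate binary annotations with a random correlation structure
#'
#' Draws latent Gaussian vectors with a random positive-definite correlation
#' matrix (see [random_correlation_matrix()]) and thresholds each coordinate
#' at the Bernoulli(`p`) quantile. Used to demonstrate that, with strongly
#' positively correlated annotations, the raw Mahalanobis length loses
#' significance as a variant's annotation load approaches saturation, while
#' the angle-based score still ranks the all-1 vector first.
#'
#' @param n_annotations number of columns (default 100).
#' @param n_variants number of rows (default 20000).
#' @param p marginal Bernoulli probability (default 0.3).
#' @param seed RNG seed (mandatory).
#' @return an [annotation_matrix()] with attribute `Sigma` (the latent
#'   correlation matrix).
#' @export
simulate_correlated_annotations <- function(n_annotations = 100,
                                            n_variants = 20000, p = 0.3,
                                            seed) {
  if (p <= 0 || p >= 1) stop("simulate_correlated_annotations: p must lie in (0, 1)")
  Sigma <- random_correlation_matrix(n_annotations, seed = seed)
  R <- chol(Sigma)
  t <- stats::qnorm(1 - p)
  Z <- matrix(stats::rnorm(n_variants * n_annotations),
              nrow = n_variants) %*% R
  values <- matrix(as.integer(Z > t), nrow = n_variants)
  mat <- annotation_matrix(simulated_variants(n_variants), values,
                           synthetic_schema(n_annotations))
  attr(mat, "Sigma") <- Sigma
  mat
}

#' Generate an on-disk toy fixture bundle
#'
#' Writes, under `dir`: BED peak tracks, the matching variants as both a
#' 3-column TSV and a VCF, a small GFF3 gene model, and the four
#' filter-cascade tables (ClinVar-like, GWAS-catalog-like, enhancer BED,
#' allele-frequency TSV) for a 10-candidate cascade with known per-step
#' survivor counts 10 -> 8 -> 7 -> 6 -> 4. All content is synthetic and
#' deterministic given the seed; the ground-truth overlap matrix is computed
#' here by a brute-force interval scan, independent of the overlap engine
#' used for scoring.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @param n_tracks number of peak tracks (default 4).
#' @param n_variants number of variants (default 12).
#' @param n_intervals intervals per track (default 5).
#' @return list with file paths (`tracks`, `variants_tsv`, `variants_vcf`,
#'   `gene_model`, `clinvar`, `gwas_catalog`, `enhancers`, `af`), the toy
#'   `schema`, the `variants` table, the ground-truth `truth_overlap`
#'   matrix, the cascade `candidates` table and `expected_cascade` counts.
#' @export
generate_fixture_tracks <- function(dir, seed = 1, n_tracks = 4,
                                    n_variants = 12, n_intervals = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  chroms <- c("1", "2")
  schema <- synthetic_schema(n_tracks, prefix = "trk")

  # peak tracks: 0-based half-open BED intervals
  tracks <- list()
  track_paths <- character(n_tracks)
  for (j in seq_len(n_tracks)) {
    starts <- sort(sample.int(5000, n_intervals)) * 10L
    ends <- starts + sample(20:200, n_intervals, replace = TRUE)
    chr <- sample(chroms, n_intervals, replace = TRUE)
    tracks[[j]] <- data.frame(chrom = chr, start = starts, end = ends,
                              stringsAsFactors = FALSE)
    track_paths[j] <- file.path(dir, sprintf("track_%s.bed",
                                             schema$annotation_id[j]))
    writeLines(sprintf("chr%s\t%d\t%d\tpk%d", chr, starts, ends,
                       seq_len(n_intervals)), track_paths[j])
  }

  # variants: half placed inside random intervals, half at random positions
  pos <- integer(n_variants); chr <- character(n_variants)
  for (i in seq_len(n_variants)) {
    if (i %% 2 == 0) {
      tr <- tracks[[sample.int(n_tracks, 1)]]
      row <- tr[sample.int(nrow(tr), 1), ]
      chr[i] <- row$chrom
      pos[i] <- sample(seq.int(row$start + 1L, row$end), 1)   # 1-based inside
    } else {
      chr[i] <- sample(chroms, 1)
      pos[i] <- sample.int(60000L, 1)
    }
  }
  variants <- variant_table(chr, pos, sprintf("fx%02d", seq_len(n_variants)))

  # ground truth by brute force: 1-based pos p overlaps [s,e) iff s <= p-1 < e
  truth <- matrix(0L, n_variants, n_tracks,
                  dimnames = list(variants$id, schema$annotation_id))
  for (i in seq_len(n_variants)) {
    for (j in seq_len(n_tracks)) {
      tr <- tracks[[j]]
      hit <- tr$chrom == variants$chrom[i] &
        tr$start <= variants$pos[i] - 1L & variants$pos[i] - 1L < tr$end
      truth[i, j] <- as.integer(any(hit))
    }
  }

  variants_tsv <- file.path(dir, "variants.tsv")
  writeLines(sprintf("chr%s\t%d\t%s", variants$chrom, variants$pos,
                     variants$id), variants_tsv)
  variants_vcf <- file.path(dir, "variants.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("chr%s\t%d\t%s\tA\tG\t.\t.\t.", variants$chrom,
                       variants$pos, variants$id)), variants_vcf)

  # gene model: two transcripts with two exons each, on chromosome 1
  gene_model <- file.path(dir, "genes.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1000\t5000\t.\t+\t.\tID=gene1",
    "chr1\ttoy\tmRNA\t1000\t5000\t.\t+\t.\tID=tx1;Parent=gene1",
    "chr1\ttoy\texon\t1000\t1100\t.\t+\t.\tID=tx1.e1;Parent=tx1",
    "chr1\ttoy\texon\t4900\t5000\t.\t+\t.\tID=tx1.e2;Parent=tx1",
    "chr1\ttoy\tgene\t20000\t26000\t.\t-\t.\tID=gene2",
    "chr1\ttoy\tmRNA\t20000\t26000\t.\t-\t.\tID=tx2;Parent=gene2",
    "chr1\ttoy\texon\t20000\t20400\t.\t-\t.\tID=tx2.e1;Parent=tx2",
    "chr1\ttoy\texon\t25500\t26000\t.\t-\t.\tID=tx2.e2;Parent=tx2"),
    gene_model)

  # filter-cascade fixture: 10 candidates, survivor counts 10 -> 8 -> 7 -> 6 -> 4
  cand <- variant_table(chrom = rep("3", 10),
                        pos = seq(1000L, by = 1000L, length.out = 10),
                        id = sprintf("rs%02d", 1:10))
  candidates_tsv <- file.path(dir, "candidates.tsv")
  writeLines(sprintf("chr%s\t%d\t%s", cand$chrom, cand$pos, cand$id),
             candidates_tsv)
  clinvar <- file.path(dir, "clinvar.tsv")
  writeLines(c("id\tclinical_significance",
               "rs01\tPathogenic",
               "rs02\tLikely pathogenic",
               "rs07\tBenign"), clinvar)
  gwas_catalog <- file.path(dir, "gwas_catalog.tsv")
  writeLines(c("id", "rs03"), gwas_catalog)
  enhancers <- file.path(dir, "enhancers.bed")
  # covers rs04 at 1-based pos 4000 (0-based 3999)
  writeLines("chr3\t3950\t4050\tenh1", enhancers)
  af <- file.path(dir, "af.tsv")
  af_tab <- data.frame(id = cand$id, AFR = 0.30, AMR = 0.25, ASN = 0.20,
                       EUR = 0.35)
  af_tab$EUR[af_tab$id == "rs05"] <- 0.04
  af_tab$ASN[af_tab$id == "rs06"] <- 0.02   # any-ancestry rule
  utils::write.table(af_tab, af, sep = "\t", quote = FALSE, row.names = FALSE)

  list(dir = dir,
       tracks = stats::setNames(track_paths, schema$annotation_id),
       variants_tsv = variants_tsv, variants_vcf = variants_vcf,
       gene_model = gene_model, clinvar = clinvar,
       gwas_catalog = gwas_catalog, enhancers = enhancers, af = af,
       candidates_tsv = candidates_tsv,
       schema = schema, variants = variants, truth_overlap = truth,
       candidates = cand, expected_cascade = c(10L, 8L, 7L, 6L, 4L))
}
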