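make_bed <- function(lines) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("BED parsing: basic line, empty file, rejected records", {
  gr <- load_peak_track(make_bed("chr1\t100\t200\tpk1"), "t1")
  expect_equal(as.character(GenomicRanges::seqnames(gr)), "1")
  expect_equal(GenomicRanges::start(gr), 101L)  # 1-based closed form of [100,200)
  expect_equal(GenomicRanges::end(gr), 200L)

  empty <- load_peak_track(make_bed(character(0)), "t0")
  expect_length(empty, 0L)

  expect_error(load_peak_track(make_bed("chr1\t200\t100"), "bad"),
               "rejected record at line 1")
  expect_error(load_peak_track(make_bed(c("chr1\t1\t10", "chr1\t5")), "bad"),
               "line 2")
  expect_error(load_peak_track(make_bed("chr1\tx\t10"), "bad"), "line 1")
})

test_that("overlap uses the standard 1-based/0-based boundary conversion", {
  tr <- load_peak_track(make_bed("chr1\t100\t200"), "t1")
  v <- variant_table(rep("1", 4), c(100L, 101L, 150L, 201L))
  m <- build_annotation_matrix(v, list(A001 = tr), synthetic_schema(1))
  # [100,200) 0-based covers 1-based 101..200: first base in, pos 100/201 out
  expect_equal(unname(m$values[, 1]), c(0L, 1L, 1L, 0L))
  v200 <- variant_table("1", 200L)
  m200 <- build_annotation_matrix(v200, list(A001 = tr), synthetic_schema(1))
  expect_equal(unname(m200$values[1, 1]), 1L)
})

test_that("matrix build matches a brute-force interval scan on random tracks", {
  set.seed(11)
  for (rep in 1:5) {
    n_tracks <- 3
    schema <- synthetic_schema(n_tracks)
    beds <- list()
    tracks <- list()
    for (j in seq_len(n_tracks)) {
      s <- sort(sample.int(2000, 8)) * 5L
      bed <- data.frame(chrom = sample(c("1", "2"), 8, replace = TRUE),
                        start = s, end = s + sample(10:100, 8, TRUE))
      beds[[j]] <- bed
      tracks[[schema$annotation_id[j]]] <-
        load_peak_track(make_bed(sprintf("chr%s\t%d\t%d", bed$chrom,
                                         bed$start, bed$end)), j)
    }
    v <- variant_table(sample(c("1", "2"), 50, TRUE), sample.int(11000, 50))
    m <- suppressWarnings(build_annotation_matrix(v, tracks, schema))
    for (j in seq_len(n_tracks)) {
      expect_equal(unname(m$values[, j]),
                   as.integer(brute_overlap(v, beds[[j]])))
    }
  }
})

test_that("matrix build is order-independent and records missing tracks as NA", {
  set.seed(12)
  tr <- load_peak_track(make_bed(c("chr1\t10\t500", "chr1\t900\t1500")), "t")
  v <- variant_table(rep("1", 6), c(20L, 600L, 1000L, 5L, 1499L, 1501L))
  schema <- synthetic_schema(2)
  m <- build_annotation_matrix(v, list(A001 = tr), schema)
  expect_true(all(is.na(m$values[, 2])))        # no track: missing, not zero
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  m2 <- build_annotation_matrix(v[perm, ], list(A001 = tr), schema)
  expect_equal(unname(m2$values[, 1]), unname(m$values[perm, 1]))
})

test_that("variants on chromosomes absent from all tracks warn, not error", {
  tr <- load_peak_track(make_bed("chr1\t10\t500"), "t")
  v <- variant_table(c("1", "7"), c(20L, 20L))
  expect_warning(
    m <- build_annotation_matrix(v, list(A001 = tr), synthetic_schema(1)),
    "absent from all tracks")
  expect_equal(unname(m$values[, 1]), c(1L, 0L))
})

test_that("list-valued tracks are aggregated by union", {
  t1 <- load_peak_track(make_bed("chr1\t0\t100"), "a")
  t2 <- load_peak_track(make_bed("chr2\t0\t100"), "b")
  v <- variant_table(c("1", "2", "3"), c(50L, 50L, 50L))
  m <- suppressWarnings(build_annotation_matrix(
    v, list(A001 = list(t1, t2)), synthetic_schema(1)))
  expect_equal(unname(m$values[, 1]), c(1L, 1L, 0L))
})

test_that("variant classification: intronic / intergenic / excluded with TSS distance", {
  fx <- generate_fixture_tracks(withr::local_tempdir(), seed = 3)
  v <- variant_table(rep("1", 4), c(2000L, 7000L, 1050L, 20100L))
  v <- classify_variants(v, fx$gene_model)
  expect_equal(v$variant_class, c("intronic", "intergenic", "excluded",
                                  "excluded"))
  # TSS at 1000 (tx1, + strand) and 26000 (tx2, - strand)
  expect_equal(v$tss_distance, c(1000L, 6000L, 50L, 5900L))
  expect_error(classify_variants(v, list(transcripts = GenomicRanges::GRanges(),
                                         exons = GenomicRanges::GRanges(),
                                         tss = GenomicRanges::GRanges())),
               "empty gene model")
})

test_that("VCF and 3-column TSV variant readers agree", {
  fx <- generate_fixture_tracks(withr::local_tempdir(), seed = 5)
  v_tsv <- read_variants(fx$variants_tsv)
  v_vcf <- read_variants(fx$variants_vcf)
  expect_equal(v_tsv$chrom, v_vcf$chrom)
  expect_equal(v_tsv$pos, v_vcf$pos)
  expect_equal(v_tsv$id, v_vcf$id)
  expect_false(any(grepl("^chr", v_tsv$chrom)))  # normalized dialect
})
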