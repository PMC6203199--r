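# Internal helpers shared across modules.

#' Normalize chromosome names to a single dialect
#'
#' Annotation tracks and variant files mix the "chr1" and "1" dialects; all
#' overlap computations in the package run on one normalized dialect.
#'
#' @param x character vector of chromosome names.
#' @param style `"strip"` (default) removes a leading `"chr"`; `"add"`
#'   prepends it where absent.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(x, style = c("strip", "add")) {
  style <- match.arg(style)
  x <- as.character(x)
  if (style == "strip") {
    sub("^chr", "", x)
  } else {
    ifelse(grepl("^chr", x), x, paste0("chr", x))
  }
}

# clamp to [-1, 1] before acos; tolerance for drift is absorbed by the clamp
clip_cosine <- function(v) pmin(1, pmax(-1, v))

#' Add-one empirical p-value
#'
#' One-sided empirical p-value of each query value against a reference sample,
#' with the add-one convention so that p is never 0: for the left tail
#' p = (1 + #\{b <= q\}) / (N + 1). Ties count towards the tail
#' (conservative).
#'
#' @param q numeric vector of query values.
#' @param reference numeric vector of reference (null) values.
#' @param tail `"left"`: small values are extreme (used for raw scores);
#'   `"right"`: large values are extreme (used for enrichment counts and
#'   diagonal angles).
#' @return numeric vector of p-values in (0, 1].
#' @export
empirical_pvalue <- function(q, reference, tail = c("left", "right")) {
  tail <- match.arg(tail)
  if (length(reference) == 0L || all(is.na(reference))) {
    stop("empirical_pvalue: reference sample is empty")
  }
  reference <- sort(reference[!is.na(reference)])
  n <- length(reference)
  if (tail == "left") {
    cnt <- findInterval(q, reference)              # #{b <= q}
  } else {
    cnt <- n - findInterval(q, reference, left.open = TRUE)  # #{b >= q}
  }
  p <- (1 + cnt) / (n + 1)
  p[is.na(q)] <- NA_real_
  p
}

# md5 of a character scalar, via a temp file (tools::md5sum is file-based)
hash_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
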