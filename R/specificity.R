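# Comparison of weighted and unweighted significance per variant, and
# detection of cell-type-specific annotation profiles via the angle to the
# main diagonal of the significance plane.

#' Signed angle to the main diagonal of the significance plane
#'
#' Axes are significance levels: `u = -log10(empirical p)` under the
#' unweighted analysis and `w = -log10(empirical p)` under the weighted one.
#' The angle is `atan2(w, u) - pi/4`, in `[-pi/4, +pi/4]` for non-negative
#' axes; positive values mean the weighted analysis is the more significant,
#' the signature of a variant whose annotations concentrate in the
#' up-weighted (phenotype-relevant) cell types. The origin `(0, 0)` has an
#' undefined angle and is reported as 0 (see `diagonal_angle_defined`).
#'
#' @param u,w non-negative significance values (vectorized).
#' @return signed angle in radians.
#' @export
diagonal_angle <- function(u, w) {
  ang <- atan2(w, u) - pi / 4
  ang[u == 0 & w == 0] <- 0
  ang
}

#' @rdname diagonal_angle
#' @return `diagonal_angle_defined`: logical, FALSE where `(u, w) = (0, 0)`.
#' @export
diagonal_angle_defined <- function(u, w) !(u == 0 & w == 0)

#' Weighted-vs-unweighted significance pairs
#'
#' Scores the query variants and the background under both an unweighted and
#' a weighted analysis (the background is re-scored under each weight
#' vector), converts empirical p-values to `-log10` significances, and
#' attaches the diagonal angle.
#'
#' @param mat [annotation_matrix()] of query variants.
#' @param background [annotation_matrix()] of background variants.
#' @param W_weighted [weight_vector()] for the weighted analysis.
#' @param k background model rank.
#' @param models optional precomputed model(s) (see [score_variants()]); by
#'   default a pooled model is estimated from `background`.
#' @return data.frame: `id`, `u`, `w`, `diagonal_angle`, `angle_defined`.
#' @export
significance_pairs <- function(mat, background, W_weighted, k = 30,
                               models = NULL) {
  if (is.null(models)) {
    models <- estimate_background_model(background, "pooled", k = k)
  }
  su <- score_variants(mat, models, background, W = NULL)
  sw <- score_variants(mat, models, background, W = W_weighted)
  u <- -log10(su$empirical_p)
  w <- -log10(sw$empirical_p)
  data.frame(id = su$id, u = u, w = w,
             diagonal_angle = diagonal_angle(u, w),
             angle_defined = diagonal_angle_defined(u, w),
             stringsAsFactors = FALSE)
}

#' Flag variants with cell-type-specific annotation profiles
#'
#' Cell-type-specific variants sit above the main diagonal of the
#' significance plane (weighted significance exceeding unweighted) and form
#' significantly larger diagonal angles than background variants. Each query
#' angle gets a one-sided add-one empirical p-value against the background
#' angles; angles at or below a configurable p threshold are flagged.
#'
#' @param query_angles numeric vector of query diagonal angles (radians).
#' @param background_angles numeric vector of background diagonal angles.
#' @param threshold flagging threshold on the angle p-value (default 0.05).
#' @return data.frame: `diagonal_angle`, `angle_p`, `flag`.
#' @export
detect_specific_variants <- function(query_angles, background_angles,
                                     threshold = 0.05) {
  if (length(background_angles) == 0L) {
    stop("detect_specific_variants: empty background angle set")
  }
  p <- empirical_pvalue(query_angles, background_angles, tail = "right")
  data.frame(diagonal_angle = query_angles, angle_p = p,
             flag = !is.na(p) & p <= threshold)
}
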