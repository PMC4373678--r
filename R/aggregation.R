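# Score totals, severity bands and genotype-level scores.

#' Total score from the ten parameter scores
#'
#' @param scores A `"parameter_scores"` object, or a numeric vector of
#'   the ten parameter scores (p3 in 0..2, others 0/1).
#' @return Integer total in 0..11.
#' @export
total_score <- function(scores) {
  if (inherits(scores, "parameter_scores"))
    scores <- unlist(scores[paste0("p", 1:10)])
  scores <- as.integer(scores)
  if (length(scores) != 10L)
    stop("expected ten parameter scores", call. = FALSE)
  if (scores[3L] < 0L || scores[3L] > 2L ||
      any(scores[-3L] < 0L) || any(scores[-3L] > 1L))
    stop("parameter score out of range", call. = FALSE)
  sum(scores)
}

#' Band a score against the catalogue mean +/- 1 SD
#'
#' `high` above `mean + sd`, `low` below `mean - sd`, `moderate`
#' otherwise (both boundaries inclusive to moderate).  The unrounded
#' mean and sample SD are used so that, on the bundled catalogue, the
#' integer thresholds fall between score values.
#'
#' @param score Numeric vector of scores.
#' @param mean,sd Centre and spread of the reference distribution
#'   (`sd > 0`).
#' @return Factor with ordered levels `low < moderate < high`.
#' @export
score_band <- function(score, mean, sd) {
  if (!is.numeric(sd) || sd <= 0) stop("sd must be positive", call. = FALSE)
  out <- ifelse(score > mean + sd, "high",
                ifelse(score < mean - sd, "low", "moderate"))
  factor(out, levels = c("low", "moderate", "high"), ordered = TRUE)
}

#' Genotype score for a two-allele genotype
#'
#' For compound heterozygotes the two allele scores are combined either
#' as their sum or as their product; the product is the better severity
#' predictor and is the package default downstream.  A product with a
#' zero-score allele is flagged `degenerate` (it carries no information
#' and is excluded from correlations by default).
#'
#' @param score_a,score_b Allele total scores in 0..11.
#' @param mode `"product"` or `"sum"`.
#' @return Object of class `"genotype_score"`: list with `mode`,
#'   `value`, `degenerate`.
#' @export
compound_score <- function(score_a, score_b, mode = c("product", "sum")) {
  mode <- match.arg(mode)
  for (s in c(score_a, score_b))
    if (!is.numeric(s) || s < 0 || s > 11)
      stop("allele scores must lie in [0, 11]", call. = FALSE)
  value <- if (mode == "product") score_a * score_b else score_a + score_b
  structure(list(mode = mode, value = value,
                 degenerate = mode == "product" && (score_a == 0 || score_b == 0)),
            class = "genotype_score")
}

#' @export
print.genotype_score <- function(x, ...) {
  cat(sprintf("<genotype score> %s = %g%s\n", x$mode, x$value,
              if (x$degenerate) " (degenerate: zero-score allele)" else ""))
  invisible(x)
}
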