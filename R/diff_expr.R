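#' Normalize a count to transcripts per million clean reads
#'
#' NE = count / total_clean x 1e6. Zero counts keep NE = 0; ratio
#' computations substitute the pseudo-expression 0.01 (see
#' [differential_expression()]), where the substitution is flagged.
#'
#' @param count Non-negative read count(s).
#' @param total_clean Total clean reads of the library (> 0).
#' @return Normalized expression per million.
#' @examples
#' normalize_expression(50, 1e6)
#' @export
normalize_expression <- function(count, total_clean) {
  if (any(total_clean <= 0)) stop("total_clean must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count / total_clean * 1e6
}

#' Log2 fold change of two normalized expressions
#'
#' @param ne1,ne2 Normalized expressions; zeros must already carry the 0.01
#'   pseudo-expression.
#' @return log2(ne1 / ne2).
#' @export
fold_change <- function(ne1, ne2) {
  if (any(ne2 <= 0) || any(ne1 <= 0))
    stop("normalized expressions must be positive (apply the 0.01 pseudo-NE)")
  log2(ne1 / ne2)
}

#' Exact two-sided P-value for a count difference between two libraries
#'
#' Conditional on the total x + y, the count y in library 2 follows
#' Binomial(x + y, N2 / (N1 + N2)) under the null of equal relative
#' expression. The two-sided P-value doubles the smaller tail (capped at 1).
#' Tail sums are computed in log space from log-gamma factorials, so large
#' counts do not overflow.
#'
#' @param x,y Read counts in libraries 1 and 2 (non-negative).
#' @param n1,n2 Total clean reads of libraries 1 and 2 (> 0).
#' @return Two-sided P-value in [0, 1]. Vectorised over `x` and `y`.
#' @examples
#' count_pvalue(10, 0, 1e6, 1e6)  # 2 * (1/2)^10
#' @export
count_pvalue <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be positive")
  vapply(seq_along(x), function(i) {
    xx <- x[i]; yy <- y[i]
    t <- xx + yy
    if (t == 0) return(1)
    q <- n2 / (n1 + n2)
    k <- 0:t
    logp <- lgamma(t + 1) - lgamma(k + 1) - lgamma(t - k + 1) +
      k * log(q) + (t - k) * log1p(-q)
    lse <- function(v) {
      if (length(v) == 0) return(-Inf)
      m <- max(v)
      m + log(sum(exp(v - m)))
    }
    lower <- lse(logp[k <= yy])
    upper <- lse(logp[k >= yy])
    min(1, 2 * min(exp(lower), exp(upper)))
  }, 0.0)
}

#' Differential expression of miRNA counts between two libraries
#'
#' Normalizes per-miRNA counts to transcripts per million, computes
#' log2(NE1/NE2) fold changes (0.01 pseudo-NE for zero counts, flagged),
#' exact conditional two-sided P-values ([count_pvalue()]), multiple-testing
#' adjusted P-values, and the three-way fold-change class: `up` when the
#' NE ratio exceeds 2, `down` when it is at most 1/2, `intermediate`
#' otherwise. A miRNA is flagged `significant` when its adjusted P-value is
#' below `p_threshold` and its class is not intermediate.
#'
#' @param counts Data frame with `name` and exactly two `count_` columns
#'   (library 1 first), e.g. the `records` table of [match_known()].
#' @param total_clean Numeric vector of length 2: total clean reads of the
#'   two libraries (defaults to the column sums of `counts`).
#' @param p_threshold Adjusted-P significance threshold (default 0.01).
#' @param fc_bounds Ratio bounds separating down/intermediate/up (default
#'   `c(0.5, 2)`).
#' @param adjust Multiple-testing method: `"BH"` (default) or `"bonferroni"`.
#' @return A `de_result` data frame: `name`, `x`, `y`, `ne1`, `ne2`,
#'   `pseudo`, `log2fc`, `p_value`, `adjusted_p`, `class`, `significant`.
#' @export
differential_expression <- function(counts, total_clean = NULL,
                                    p_threshold = 0.01,
                                    fc_bounds = c(0.5, 2),
                                    adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  cols <- grep("^count_", names(counts), value = TRUE)
  if (length(cols) != 2)
    stop("need exactly two count_ columns, got ", length(cols))
  x <- counts[[cols[1]]]
  y <- counts[[cols[2]]]
  if (is.null(total_clean)) total_clean <- c(sum(x), sum(y))
  ne1 <- normalize_expression(x, total_clean[1])
  ne2 <- normalize_expression(y, total_clean[2])
  pseudo <- ne1 == 0 | ne2 == 0
  ne1r <- ifelse(ne1 == 0, 0.01, ne1)
  ne2r <- ifelse(ne2 == 0, 0.01, ne2)
  log2fc <- fold_change(ne1r, ne2r)
  ratio <- ne1r / ne2r
  cls <- ifelse(ratio > fc_bounds[2], "up",
                ifelse(ratio <= fc_bounds[1], "down", "intermediate"))
  p <- count_pvalue(x, y, total_clean[1], total_clean[2])
  adj <- stats::p.adjust(p, method = adjust)
  out <- data.frame(
    name = counts$name, x = x, y = y, ne1 = ne1, ne2 = ne2,
    pseudo = pseudo, log2fc = log2fc, p_value = p, adjusted_p = adj,
    class = cls, significant = adj < p_threshold & cls != "intermediate",
    stringsAsFactors = FALSE
  )
  class(out) <- c("de_result", "data.frame")
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' N = 2^-((Ct_target_sample - Ct_ref_sample) -
#'          (Ct_target_calibrator - Ct_ref_calibrator)).
#'
#' @param ct_target_sample,ct_ref_sample Threshold cycles of the target and
#'   reference gene in the sample of interest.
#' @param ct_target_calib,ct_ref_calib Threshold cycles in the calibrator.
#' @return Relative expression N.
#' @examples
#' ddct(20, 15, 18, 16)  # ddCt = 3 -> 0.125
#' @export
ddct <- function(ct_target_sample, ct_ref_sample, ct_target_calib,
                 ct_ref_calib) {
  ddct_val <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calib - ct_ref_calib)
  2^(-ddct_val)
}

#' Log2-ratio scatter plot of a differential expression result
#'
#' Plots library-2 against library-1 normalized expression on log scales,
#' coloured by fold-change class: red for ratio > 2, blue for intermediate,
#' green for ratio <= 1/2.
#'
#' @param de A [differential_expression()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_de <- function(de, ...) {
  col <- c(up = "red", intermediate = "blue", down = "green")[de$class]
  graphics::plot(pmax(de$ne1, 0.01), pmax(de$ne2, 0.01), log = "xy",
                 col = col, pch = 20,
                 xlab = "Normalized expression, library 1 (TPM)",
                 ylab = "Normalized expression, library 2 (TPM)", ...)
  graphics::abline(0, 1, untf = TRUE, lty = 2, col = "grey40")
  invisible(de)
}
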