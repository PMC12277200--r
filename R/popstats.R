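## Population statistics: per-cohort actionable summaries and two-cohort
## comparison (pooled two-proportion z-test, Wald difference CI, odds
## ratio with Woolf CI and Haldane-Anscombe zero-cell correction,
## Benjamini-Hochberg correction across the tested drugs).

#' Summarize a classified cohort
#'
#' Per-drug actionable counts, proportions and percentages. Indeterminate
#' (flagged) samples are excluded from numerators but kept in the
#' denominator (the cohort size), so percentages are per total cohort.
#' Percentages are stored at full precision; report writers round to one
#' decimal.
#'
#' @param classification data.frame from [classifyCohort()], or a data.frame
#'   with columns \code{drug}, \code{actionable} and optionally
#'   \code{sample_id}, \code{category}, \code{flagged}.
#' @param label Cohort label.
#' @param n Cohort size; defaults to the number of distinct samples.
#' @return A [CohortSummary-class].
#' @export
#' @examples
#' # printed-count arithmetic: 8420 of 14354 -> 58.7%
#' cls <- data.frame(drug = "citalopram_escitalopram",
#'                   actionable = rep(c(TRUE, FALSE), c(8420, 14354 - 8420)))
#' cohortStats(summarizeCohort(cls, "QGP", n = 14354))$percent
summarizeCohort <- function(classification, label, n = NULL) {
  if (is.null(n)) {
    if (!"sample_id" %in% names(classification))
      stop("supply n when classification has no sample_id column")
    n <- length(unique(classification$sample_id))
  }
  if (n < 1L || nrow(classification) == 0L) stop("empty cohort")
  drugsIn <- unique(classification$drug)
  x <- vapply(drugsIn, function(d)
    sum(classification$actionable[classification$drug == d]), 0L)
  fl <- if ("flagged" %in% names(classification))
    vapply(drugsIn, function(d)
      sum(classification$flagged[classification$drug == d]), 0L)
  else rep(0L, length(drugsIn))
  stats <- data.frame(drug = drugsIn, actionable = as.integer(x),
                      proportion = x / n, percent = 100 * x / n,
                      flagged = as.integer(fl), stringsAsFactors = FALSE,
                      row.names = NULL)
  hist <- list()
  if ("category" %in% names(classification)) {
    for (d in drugsIn) {
      cats <- classification$category[classification$drug == d]
      if (!all(is.na(cats)))
        hist[[d]] <- table(cats[!is.na(cats)])
    }
  }
  new("CohortSummary", label = label, n = as.integer(n), stats = stats,
      histograms = hist)
}

#' Pooled two-proportion z-test
#'
#' Pooled-variance z statistic without continuity correction (so that
#' z^2 equals the uncorrected chi-square statistic on the same 2x2
#' table), two-sided p, and a Wald confidence interval for p1 - p2.
#' Degenerate tables with no variance (both proportions 0 or both 1)
#' return z = 0, p = 1 with \code{degenerate = TRUE}. p-values are never
#' exactly 0: they are floored at the smallest positive double with
#' \code{p_floored = TRUE}.
#'
#' @param x1,n1,x2,n2 Successes and sizes of the two arms.
#' @param conf.level Confidence level for the difference CI (default 0.95).
#' @return List with \code{z}, \code{p}, \code{estimate} (p1 - p2),
#'   \code{conf.int}, \code{degenerate}, \code{p_floored}.
#' @export
twoProportionZTest <- function(x1, n1, x2, n2, conf.level = 0.95) {
  if (n1 <= 0 || n2 <= 0) stop("arm sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("counts must satisfy 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  zcrit <- stats::qnorm(1 - (1 - conf.level) / 2)
  se_wald <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  ci <- (p1 - p2) + c(-1, 1) * zcrit * se_wald
  if (pp == 0 || pp == 1)
    return(list(z = 0, p = 1, estimate = p1 - p2, conf.int = ci,
                degenerate = TRUE, p_floored = FALSE))
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  p <- 2 * stats::pnorm(-abs(z))
  floored <- p == 0
  if (floored) p <- .Machine$double.xmin
  list(z = z, p = p, estimate = p1 - p2, conf.int = ci,
       degenerate = FALSE, p_floored = floored)
}

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio for the 2x2 table
#' \code{(x1, n1 - x1; x2, n2 - x2)} with a log-scale (Woolf) CI. When any
#' cell is zero the Haldane-Anscombe correction (+0.5 to every cell) is
#' applied and \code{corrected = TRUE}.
#'
#' @inheritParams twoProportionZTest
#' @return List with \code{or}, \code{conf.int}, \code{corrected}.
#' @export
oddsRatio <- function(x1, n1, x2, n2, conf.level = 0.95) {
  if (n1 <= 0 || n2 <= 0) stop("arm sizes must be positive")
  a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  zcrit <- stats::qnorm(1 - (1 - conf.level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, conf.int = exp(log(or) + c(-1, 1) * zcrit * se),
       corrected = corrected)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via \code{stats::p.adjust}) with input
#' validation: adjusted values dominate the raw ones, preserve the raw-p
#' ordering and are capped at 1.
#'
#' @param pvals Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Compare actionable proportions between two cohorts
#'
#' Per drug: pooled two-proportion z-test, Wald difference CI, odds ratio
#' with Woolf CI, then Benjamini-Hochberg correction across the drug list.
#' Two significance flags are reported: \code{significant} (adjusted
#' p below \code{alpha}) and \code{significant_genomewide} (adjusted
#' p below \code{alphaGenomewide}).
#'
#' @param a,b [CohortSummary-class] objects covering the same drug list.
#' @param m Number of tests for the BH correction; defaults to the number
#'   of drugs in the summaries.
#' @param alpha BH significance threshold (default 0.05).
#' @param alphaGenomewide Genome-wide threshold (default 5e-8).
#' @param conf.level CI level (default 0.95).
#' @return data.frame with one row per drug: counts, proportions,
#'   \code{z}, \code{p}, \code{p_adj}, difference CI bounds, odds ratio
#'   and CI bounds, and the two significance flags.
#' @export
compareCohorts <- function(a, b, m = NULL, alpha = 0.05,
                           alphaGenomewide = 5e-8, conf.level = 0.95) {
  sa <- cohortStats(a); sb <- cohortStats(b)
  if (!setequal(sa$drug, sb$drug))
    stop("cohort summaries cover different drug lists")
  sb <- sb[match(sa$drug, sb$drug), ]
  n1 <- cohortSize(a); n2 <- cohortSize(b)
  rows <- lapply(seq_len(nrow(sa)), function(i) {
    zt <- twoProportionZTest(sa$actionable[i], n1, sb$actionable[i], n2,
                             conf.level = conf.level)
    or <- oddsRatio(sa$actionable[i], n1, sb$actionable[i], n2,
                    conf.level = conf.level)
    data.frame(drug = sa$drug[i], x1 = sa$actionable[i], n1 = n1,
               x2 = sb$actionable[i], n2 = n2,
               p1 = sa$proportion[i], p2 = sb$proportion[i],
               diff = zt$estimate, z = zt$z, p = zt$p,
               ci_lo = zt$conf.int[1], ci_hi = zt$conf.int[2],
               or = or$or, or_lo = or$conf.int[1], or_hi = or$conf.int[2],
               degenerate = zt$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(m)) m <- nrow(out)
  if (m < nrow(out))
    stop("m must be at least the number of drugs tested (", nrow(out), ")")
  ## BH over m tests: pad conceptually with tests at p = 1 changes nothing
  ## in the step-up ordering beyond the m multiplier, so adjust directly.
  padded <- c(out$p, rep(1, m - nrow(out)))
  out$p_adj <- bhAdjust(padded)[seq_len(nrow(out))]
  out$significant <- out$p_adj < alpha
  out$significant_genomewide <- out$p_adj < alphaGenomewide
  rownames(out) <- NULL
  out
}
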