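.checkCounts <- function(Pn, Ps, Dn, Ds) {
  v <- c(Pn, Ps, Dn, Ds)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
    stop("Pn, Ps, Dn, Ds must be non-negative integers")
}

#' Fisher exact test of a McDonald-Kreitman table
#'
#' Two-sided Fisher exact p for the 2x2 contingency table
#' \code{[[Pn, Ps], [Dn, Ds]]} (polymorphism vs divergence, non-synonymous
#' vs synonymous).  Degenerate tables with an all-zero row or column return
#' p = 1 by convention.
#'
#' @param Pn,Ps,Dn,Ds non-negative integer counts.
#' @return the two-sided p-value.
#' @export
mktFisher <- function(Pn, Ps, Dn, Ds) {
  .checkCounts(Pn, Ps, Dn, Ds)
  if ((Pn + Ps) == 0 || (Dn + Ds) == 0 || (Pn + Dn) == 0 || (Ps + Ds) == 0)
    return(1)
  m <- matrix(c(Pn, Ps, Dn, Ds), nrow = 2L, byrow = TRUE)
  # exact p can exceed 1 by a few ulp when the table is near-proportional
  min(1, stats::fisher.test(m, alternative = "two.sided")$p.value)
}

#' Estimate the proportion of adaptive substitutions (alpha)
#'
#' The standard MKT estimator \code{alpha = 1 - (Ds * Pn) / (Dn * Ps)}.
#' Undefined (returns \code{NA}) when \code{Dn = 0} or \code{Ps = 0}.
#'
#' @param Pn,Ps,Dn,Ds non-negative counts (vectorised).
#' @return numeric alpha estimate(s), \code{NA} where undefined.
#' @examples
#' alphaEstimate(2, 10, 10, 5)  # 0.9
#' @export
alphaEstimate <- function(Pn, Ps, Dn, Ds) {
  Pn <- as.numeric(Pn); Ps <- as.numeric(Ps)
  Dn <- as.numeric(Dn); Ds <- as.numeric(Ds)
  ifelse(Dn == 0 | Ps == 0, NA_real_, 1 - (Ds * Pn) / (Dn * Ps))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values for a vector of p-values.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values of the same length.
#' @export
fdrAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-gene MKT with FDR correction
#'
#' Adds the Fisher p, BH q, alpha and the table odds ratio
#' \code{(Pn * Ds) / (Ps * Dn)} (values below 1 indicate a Dn/Ds excess,
#' the direction compatible with positive selection) to an MKT count table.
#'
#' @param tables data.frame with columns \code{gene_id, Pn, Ps, Dn, Ds}
#'   (extra columns are carried through).
#' @return the data.frame with \code{p_fisher}, \code{q_fdr}, \code{alpha}
#'   and \code{odds_ratio} columns appended.
#' @export
mktTest <- function(tables) {
  need <- c("gene_id", "Pn", "Ps", "Dn", "Ds")
  if (!all(need %in% names(tables)))
    stop("tables must have columns: ", paste(need, collapse = ", "))
  tables$p_fisher <- mapply(mktFisher, tables$Pn, tables$Ps, tables$Dn,
                            tables$Ds)
  tables$q_fdr <- fdrAdjust(tables$p_fisher)
  tables$alpha <- alphaEstimate(tables$Pn, tables$Ps, tables$Dn, tables$Ds)
  tables$odds_ratio <- ifelse(tables$Ps * tables$Dn == 0, NA_real_,
                              (tables$Pn * tables$Ds) /
                                (tables$Ps * tables$Dn))
  tables
}

#' Pooled (concatenated) alpha of a gene collection
#'
#' Sums Pn, Ps, Dn, Ds across genes and applies the alpha estimator to the
#' pooled counts.
#'
#' @param tables data.frame with columns \code{Pn, Ps, Dn, Ds}.
#' @return pooled alpha (\code{NA} when the pooled table is degenerate).
#' @export
concatenateAlpha <- function(tables) {
  if (nrow(tables) == 0L) stop("at least one table is required")
  alphaEstimate(sum(tables$Pn), sum(tables$Ps), sum(tables$Dn),
                sum(tables$Ds))
}

#' Bootstrap contrast of pooled alpha between two gene sets
#'
#' Per group, draws k genes with replacement B times; each draw's alpha is
#' the pooled (concatenated) estimate.  Draws with undefined alpha are
#' redrawn (bounded retries).  The two bootstrap alpha collections are
#' compared by an unpaired t test (Student by default, Welch selectable).
#'
#' @param groupA,groupB data.frames of MKT counts (one row per gene).
#' @param k genes per draw (default 30).
#' @param B draws per group (default 100).
#' @param seed optional RNG seed.
#' @param variant \code{"student"} (equal-variance, default) or
#'   \code{"welch"}.
#' @param maxRetries redraw budget per draw before erroring.
#' @return list: \code{alphaA}, \code{alphaB} (length-B samples),
#'   \code{meanA}, \code{meanB}, \code{sdA}, \code{sdB}, \code{tStatistic},
#'   \code{pValue}, \code{k}, \code{B}, \code{nRedraws}.
#' @export
bootstrapAlphaComparison <- function(groupA, groupB, k = 30L, B = 100L,
                                     seed = NULL,
                                     variant = c("student", "welch"),
                                     maxRetries = 100L) {
  variant <- match.arg(variant)
  if (nrow(groupA) < 1L || nrow(groupB) < 1L)
    stop("each group needs at least one gene")
  if (k < 1L || B < 1L) stop("k and B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  redraws <- 0L
  drawOne <- function(tab) {
    for (try in seq_len(maxRetries + 1L)) {
      a <- concatenateAlpha(tab[sample.int(nrow(tab), k, replace = TRUE), ,
                                drop = FALSE])
      if (!is.na(a)) return(a)
      redraws <<- redraws + 1L
    }
    stop("bootstrap draw kept yielding undefined alpha after ",
         maxRetries, " retries")
  }
  alphaA <- vapply(seq_len(B), function(i) drawOne(groupA), numeric(1))
  alphaB <- vapply(seq_len(B), function(i) drawOne(groupB), numeric(1))
  if (redraws > 0L)
    message("bootstrapAlphaComparison: ", redraws,
            " draw(s) redrawn due to undefined alpha")
  tt <- stats::t.test(alphaA, alphaB, var.equal = (variant == "student"))
  list(alphaA = alphaA, alphaB = alphaB,
       meanA = mean(alphaA), meanB = mean(alphaB),
       sdA = stats::sd(alphaA), sdB = stats::sd(alphaB),
       tStatistic = unname(tt$statistic), pValue = tt$p.value,
       k = as.integer(k), B = as.integer(B), nRedraws = redraws)
}

#' Read an MKT count table from TSV
#'
#' @param path TSV with columns \code{gene_id, Pn, Ps, Dn, Ds} and
#'   optionally \code{group}.
#' @return data.frame of counts.
#' @export
readMKTCounts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "Pn", "Ps", "Dn", "Ds")
  if (!all(need %in% names(tab)))
    stop(path, " must have columns: ", paste(need, collapse = ", "))
  .checkCounts(tab$Pn, tab$Ps, tab$Dn, tab$Ds)
  tab
}
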