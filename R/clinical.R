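#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Estimates the allele frequency from the counts, forms the expected
#' genotype counts (n p^2, 2 n p q, n q^2) and computes the Pearson
#' chi-square statistic with 1 degree of freedom.
#'
#' @param n_MM,n_MV,n_VV genotype counts (>= 0, positive total).
#' @return list with \code{chi2}, \code{df} (= 1), \code{p},
#'   \code{allele_freq} (frequency of the M allele) and \code{expected}
#'   counts.
#' @export
hwe_test <- function(n_MM, n_MV, n_VV) {
  obs <- c(n_MM, n_MV, n_VV)
  if (any(obs < 0)) stop("counts must be >= 0")
  n <- sum(obs)
  if (n == 0) stop("zero total count")
  p <- (2 * n_MM + n_MV) / (2 * n)
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  ok <- expected > 0
  chi2 <- sum((obs[ok] - expected[ok])^2 / expected[ok])
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       allele_freq = p, expected = expected)
}

#' Two-group scalar comparison
#'
#' Continuous variables are compared with the two-sided pooled-variance
#' Student t test; categorical variables with the Pearson chi-square test
#' (no continuity correction by default).
#'
#' @param values vector of observations (numeric, or category labels for
#'   \code{kind = "categorical"}).
#' @param groups vector of two group labels, same length as \code{values}.
#' @param kind \code{"continuous"} or \code{"categorical"}.
#' @param welch use the Welch t test instead of pooled variance.
#' @param correct apply the Yates continuity correction to the chi-square.
#' @return list with \code{statistic}, \code{df}, \code{p} and either group
#'   means/SDs or the contingency table.
#' @export
compare_groups_scalar <- function(values, groups,
                                  kind = c("continuous", "categorical"),
                                  welch = FALSE, correct = FALSE) {
  kind <- match.arg(kind)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) stop("exactly two groups required")
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (kind == "continuous") {
    if (any(table(groups) < 2)) stop("each group needs n >= 2")
    tt <- stats::t.test(values ~ groups, var.equal = !welch)
    means <- tapply(values, groups, mean)
    sds <- tapply(values, groups, stats::sd)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, means = means, sds = sds,
         n = as.vector(table(groups)))
  } else {
    tab <- table(values, groups)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value, table = tab)
  }
}

#' ROI-volume x behavior Pearson correlation table
#'
#' For every combination of genotype group, ROI column and score column,
#' computes the Pearson correlation and its two-sided p-value, with
#' significance flags at 0.05 (\code{*}) and 0.01 (\code{**}) as customarily
#' footnoted in correlation tables. Cells with fewer than 3 paired
#' observations or a constant column are NA. Flags are on the raw p-values
#' by default; set \code{adjust = "BH"} for Benjamini-Hochberg-adjusted
#' flags.
#'
#' @param volume_table subjects x ROIs matrix (e.g. from
#'   \code{\link{extract_volumes}} or \code{\link{peak_sphere_volumes}}).
#' @param phenotypes phenotype data.frame aligned with the rows.
#' @param scores character vector of score columns (default: all columns
#'   after the fixed identifier columns).
#' @param by_group split by genotype group (default TRUE).
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame of class \code{scn_cortable} with columns
#'   \code{score, roi, group, n, r, p, flag}.
#' @export
correlate_volumes_scores <- function(volume_table, phenotypes,
                                     scores = NULL, by_group = TRUE,
                                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(volume_table) != nrow(phenotypes)) {
    stop("volume table and phenotypes must have the same rows")
  }
  if (is.null(scores)) {
    scores <- setdiff(names(phenotypes), phenotype_id_cols)
  }
  if (length(scores) == 0) stop("no score columns")
  grp <- if (by_group) phenotypes$group else rep("all", nrow(phenotypes))
  cells <- expand.grid(score = scores, roi = colnames(volume_table),
                       group = unique(grp), stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    g <- grp == cells$group[i]
    x <- volume_table[g, cells$roi[i]]
    y <- phenotypes[[cells$score[i]]][g]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(c(n = n, r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    c(n = n, r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  out <- cbind(cells, as.data.frame(res))
  pf <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$flag <- ifelse(is.na(pf), "",
                     ifelse(pf < 0.01, "**", ifelse(pf < 0.05, "*", "")))
  class(out) <- c("scn_cortable", class(out))
  out
}

# "32, 35.16%" style count-percentage cell
format_count_pct <- function(count, n) {
  sprintf("%d, %.2f%%", count, if (n > 0) 100 * count / n else 0)
}

#' Demographics and neurobehavioral comparison table
#'
#' Per variable: group mean +/- SD (continuous; pooled-variance t test) or
#' count with percentage (categorical; chi-square test), with the between-
#' group p-value. Percentages are 100 * count / group size, to two decimals.
#'
#' @param phenotypes phenotype data.frame.
#' @param continuous,categorical variable names; defaults cover age,
#'   education and every score column (continuous) plus sex and apoe4
#'   (categorical).
#' @return data.frame with columns \code{variable, met, val, p}.
#' @export
demographics_report <- function(phenotypes,
                                continuous = NULL, categorical = NULL) {
  check_phenotypes(phenotypes)
  if (is.null(continuous)) {
    continuous <- c("age", "education",
                    setdiff(names(phenotypes), phenotype_id_cols))
  }
  if (is.null(categorical)) categorical <- c("sex", "apoe4")
  grp <- phenotypes$group
  n_met <- sum(grp == "Met"); n_val <- sum(grp == "Val")
  rows <- list(data.frame(variable = "n", met = as.character(n_met),
                          val = as.character(n_val), p = NA_real_))
  for (v in continuous) {
    x <- phenotypes[[v]]
    cmp <- compare_groups_scalar(x, grp, "continuous")
    rows[[length(rows) + 1]] <- data.frame(
      variable = v,
      met = sprintf("%.2f ± %.2f", cmp$means[["Met"]],
                    cmp$sds[["Met"]]),
      val = sprintf("%.2f ± %.2f", cmp$means[["Val"]],
                    cmp$sds[["Val"]]),
      p = cmp$p)
  }
  for (v in categorical) {
    x <- phenotypes[[v]]
    cmp <- compare_groups_scalar(x, grp, "categorical")
    lev <- sort(unique(x), decreasing = TRUE)[1]  # "positive" level
    cm <- sum(x == lev & grp == "Met"); cv <- sum(x == lev & grp == "Val")
    rows[[length(rows) + 1]] <- data.frame(
      variable = paste0(v, " (", lev, ")"),
      met = format_count_pct(cm, n_met),
      val = format_count_pct(cv, n_val),
      p = cmp$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
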