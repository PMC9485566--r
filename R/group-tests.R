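# Distribution-free group comparisons: Wilcoxon signed rank for paired
# samples, Mann-Whitney U for unpaired samples, Friedman or
# Kruskal-Wallis ANOVA for several samples with Dunn's post hoc, and the
# 2x2 chi-square for proportions.

#' Nonparametric group comparison dispatcher
#'
#' Runs the rank test matching the design: Wilcoxon signed rank
#' (`paired`), Mann-Whitney U (`unpaired`), Kruskal-Wallis with Dunn's
#' post hoc (`k_unpaired`), or Friedman with Dunn-style post hoc on the
#' within-block ranks (`k_paired`). Post hoc p-values are
#' Bonferroni-adjusted. Ties are handled by midranks with a normal
#' approximation (the stats defaults); identical paired samples (all
#' zero differences) are reported with p = 1 rather than an error.
#'
#' @param samples list of numeric vectors (2 for `paired`/`unpaired`,
#'   >= 3 groups allowed for the k-sample designs). Paired designs
#'   require equal lengths.
#' @param design `"unpaired"`, `"paired"`, `"k_unpaired"`, `"k_paired"`.
#' @param alpha significance level used to flag post hoc pairs.
#' @return list of class `test_report`: `method`, `statistic`,
#'   `p_value`, `n` per group, and for k-sample designs a `posthoc`
#'   data.frame (pair, z, p_raw, p_adj, significant).
#' @export
group_compare <- function(samples,
                          design = c("unpaired", "paired", "k_unpaired", "k_paired"),
                          alpha = 0.05) {
  design <- match.arg(design)
  if (!is.list(samples) || length(samples) < 2)
    stop_invalid("samples must be a list of at least 2 numeric vectors")
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  n <- vapply(samples, length, integer(1))
  if (any(n < 3)) stop_invalid("each group needs at least 3 observations")

  if (design %in% c("paired", "unpaired") && length(samples) != 2)
    stop_invalid("two-sample designs need exactly 2 groups")
  if (design %in% c("paired", "k_paired") && length(unique(n)) != 1)
    stop_invalid("paired designs require equal group lengths")

  out <- switch(design,
    paired = {
      d <- samples[[1]] - samples[[2]]
      if (all(d == 0)) {
        list(method = "Wilcoxon signed rank", statistic = 0, p_value = 1,
             note = "all paired differences zero")
      } else {
        wt <- suppressWarnings(stats::wilcox.test(samples[[1]], samples[[2]],
                                                  paired = TRUE))
        list(method = "Wilcoxon signed rank", statistic = unname(wt$statistic),
             p_value = wt$p.value)
      }
    },
    unpaired = {
      wt <- suppressWarnings(stats::wilcox.test(samples[[1]], samples[[2]]))
      list(method = "Mann-Whitney U", statistic = unname(wt$statistic),
           p_value = wt$p.value)
    },
    k_unpaired = {
      kt <- stats::kruskal.test(samples)
      list(method = "Kruskal-Wallis", statistic = unname(kt$statistic),
           p_value = kt$p.value,
           posthoc = dunn_posthoc(samples, alpha))
    },
    k_paired = {
      m <- do.call(cbind, samples)
      ft <- stats::friedman.test(m)
      list(method = "Friedman", statistic = unname(ft$statistic),
           p_value = ft$p.value,
           posthoc = friedman_posthoc(m, alpha))
    })
  out$design <- design
  out$n <- n
  out$alpha <- alpha
  structure(out, class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value, paste(x$n, collapse = ", ")))
  if (!is.null(x$posthoc)) {
    cat("  Dunn post hoc (Bonferroni):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

# Dunn's post hoc on pooled midranks after Kruskal-Wallis, with the
# usual tie correction and Bonferroni adjustment.
dunn_posthoc <- function(samples, alpha = 0.05) {
  g <- names(samples)
  x <- unlist(samples, use.names = FALSE)
  grp <- rep(g, vapply(samples, length, integer(1)))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  rbar <- tapply(r, grp, mean)
  ni <- tapply(r, grp, length)
  pairs <- utils::combn(g, 2, simplify = FALSE)
  m <- length(pairs)
  res <- do.call(rbind, lapply(pairs, function(p) {
    z <- (rbar[p[1]] - rbar[p[2]]) /
      sqrt(s2 * (1 / ni[p[1]] + 1 / ni[p[2]]))
    praw <- 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste(p, collapse = " vs "), z = unname(z),
               p_raw = unname(praw), p_adj = unname(min(1, praw * m)))
  }))
  res$significant <- res$p_adj < alpha
  res
}

# Post hoc for Friedman: z on within-block mean ranks.
friedman_posthoc <- function(m, alpha = 0.05) {
  k <- ncol(m); n <- nrow(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("group", seq_len(k))
  rks <- t(apply(m, 1, rank))
  rbar <- colMeans(rks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(colnames(m), 2, simplify = FALSE)
  mm <- length(pairs)
  res <- do.call(rbind, lapply(pairs, function(p) {
    z <- (rbar[p[1]] - rbar[p[2]]) / se
    praw <- 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste(p, collapse = " vs "), z = unname(z),
               p_raw = unname(praw), p_adj = unname(min(1, praw * mm)))
  }))
  res$significant <- res$p_adj < alpha
  res
}

#' Compare two proportions with a 2x2 chi-square test
#'
#' E.g. percentages of neurons with and without spontaneous firing, or
#' of indented vs smooth phase plots, between conditions.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @param correct logical; apply Yates continuity correction (off by
#'   default, matching the plain df = 1 chi-square).
#' @return list with `chi_sq`, `df` (1), `p_value`, `proportions`.
#' @export
proportion_compare <- function(k1, n1, k2, n2, correct = FALSE) {
  for (v in list(k1, n1, k2, n2))
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      stop_invalid("counts must be single non-negative integers")
  if (n1 == 0 || n2 == 0) stop_invalid("group totals must be positive")
  if (k1 > n1 || k2 > n2) stop_invalid("successes cannot exceed totals")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
  if (k1 / n1 == k2 / n2) {
    # identical proportions: chi-square is exactly 0
    return(list(chi_sq = 0, df = 1L, p_value = 1,
                proportions = c(k1 / n1, k2 / n2)))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi_sq = unname(ct$statistic), df = 1L, p_value = ct$p.value,
       proportions = c(k1 / n1, k2 / n2))
}
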