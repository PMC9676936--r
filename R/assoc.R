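# Group-wise trait association: Wilcoxon rank-sum, Student and Welch
# t-tests for two groups, Tukey HSD with a compact letter display for
# multiple groups. No multiple-testing correction by default, matching the
# per-trait alpha = 0.05 convention; a Benjamini-Hochberg option is
# available.

#' Two-group trait tests
#'
#' Runs the Wilcoxon rank-sum test (exact when combined n <= 50 and no
#' ties, else normal approximation with continuity correction), Student's
#' t-test and Welch's t-test, two-sided. When both groups are identical
#' with zero variance the tests are degenerate: p = 1 by convention,
#' flagged.
#'
#' @param values numeric trait values
#' @param groups two-level grouping vector
#' @param alpha significance level (default 0.05)
#' @return data.frame with one row per test: test, statistic, p_value,
#'   mean1, mean2, direction, significant, flag
#' @export
pairwiseTests <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  x <- values[groups == lv[1]]; y <- values[groups == lv[2]]
  if (length(x) < 3 || length(y) < 3) stop("each group needs n >= 3")
  m1 <- mean(x); m2 <- mean(y)
  dir <- if (m1 > m2) paste(lv[1], ">", lv[2]) else paste(lv[1], "<", lv[2])
  degenerate <- sd(c(x, y)) == 0
  mk <- function(test, stat, p, flag = "") {
    data.frame(test = test, statistic = stat, p_value = p, mean1 = m1,
               mean2 = m2, group1 = lv[1], group2 = lv[2], direction = dir,
               significant = p <= alpha, flag = flag,
               stringsAsFactors = FALSE)
  }
  if (degenerate) {
    return(rbind(mk("wilcoxon", NA_real_, 1, "degenerate"),
                 mk("student_t", NA_real_, 1, "degenerate"),
                 mk("welch_t", NA_real_, 1, "degenerate")))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 50 && !ties
  w <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  ts <- t.test(x, y, var.equal = TRUE)
  tw <- t.test(x, y, var.equal = FALSE)
  rbind(mk("wilcoxon", unname(w$statistic), w$p.value),
        mk("student_t", unname(ts$statistic), ts$p.value),
        mk("welch_t", unname(tw$statistic), tw$p.value))
}

# compact letter display by insert-and-absorb over significant pairs
.letterDisplay <- function(levelsV, sigPairs) {
  cols <- list(levelsV)
  for (i in seq_len(nrow(sigPairs))) {
    a <- sigPairs[i, 1]; b <- sigPairs[i, 2]
    newCols <- list()
    for (cset in cols) {
      if (a %in% cset && b %in% cset) {
        newCols <- c(newCols, list(setdiff(cset, a)), list(setdiff(cset, b)))
      } else newCols <- c(newCols, list(cset))
    }
    # absorb: drop columns that are subsets of other columns
    keep <- rep(TRUE, length(newCols))
    for (u in seq_along(newCols)) for (v in seq_along(newCols)) {
      if (u != v && keep[u] && keep[v] &&
          all(newCols[[u]] %in% newCols[[v]]) &&
          (length(newCols[[u]]) < length(newCols[[v]]) || u > v))
        keep[u] <- FALSE
    }
    cols <- newCols[keep]
  }
  # order columns by the first level they contain
  firstIdx <- vapply(cols, function(cset) min(match(cset, levelsV)), 0)
  cols <- cols[order(firstIdx)]
  lab <- setNames(rep("", length(levelsV)), levelsV)
  for (ci in seq_along(cols))
    for (g in cols[[ci]]) lab[g] <- paste0(lab[g], letters[ci])
  lab
}

#' Tukey HSD with compact letter display
#'
#' Pairwise studentized-range comparisons over k groups; groups sharing a
#' letter are not significantly different at \code{alpha}.
#'
#' @param values numeric trait values
#' @param groups grouping vector (k >= 2 levels, each n >= 2)
#' @param alpha significance level
#' @return list: pairs (data.frame of pairwise comparisons), letters
#'   (named by group), means, flag ("" or "singular")
#' @export
tukeyHsd <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(as.character(groups)[ok])
  if (nlevels(groups) < 2) stop("need k >= 2 groups")
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  means <- tapply(values, groups, mean)
  fit <- aov(values ~ groups)
  flag <- ""
  if (summary(fit)[[1]]["Residuals", "Mean Sq"] <= 0) {
    flag <- "singular"
    letters_ <- setNames(rep("a", nlevels(groups)), levels(groups))
    return(list(pairs = NULL, letters = letters_, means = means, flag = flag))
  }
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pairsDf <- data.frame(
    comparison = rownames(tk), diff = tk[, "diff"], p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] <= alpha, row.names = NULL,
    stringsAsFactors = FALSE)
  sp <- do.call(rbind, strsplit(pairsDf$comparison[pairsDf$significant], "-",
                                fixed = TRUE))
  if (is.null(sp)) sp <- matrix(character(0), 0, 2)
  letters_ <- .letterDisplay(levels(groups), sp)
  list(pairs = pairsDf, letters = letters_, means = means, flag = flag)
}

#' Full trait-by-grouping association report
#'
#' Tests every trait against every grouping: two-level groupings with the
#' Wilcoxon, Student and Welch tests (disagreements at \code{alpha} are
#' flagged), multi-level groupings with Tukey HSD. Groups smaller than 3
#' are dropped from two-level tests.
#'
#' @param traitTable data.frame from \code{\link{simulatePhenotypes}} (or
#'   equivalent: sample column, grouping columns, numeric trait columns)
#' @param groupings names of grouping columns
#' @param traits names of trait columns (default: all numeric columns)
#' @param alpha significance level
#' @param adjust "none" (default, per-trait alpha) or "BH"
#' @return data.frame with one row per trait x grouping
#' @export
associationReport <- function(traitTable, groupings = "group", traits = NULL,
                              alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(traits))
    traits <- names(traitTable)[vapply(traitTable, is.numeric, TRUE) &
                                  !names(traitTable) %in% groupings]
  rows <- list()
  for (g in groupings) {
    glab <- as.character(traitTable[[g]])
    tab <- table(glab)
    lv <- names(tab)[tab >= 3]
    if (length(lv) < 2) {
      warning("grouping '", g, "' has fewer than two usable groups; skipped")
      next
    }
    for (tr in traits) {
      v <- traitTable[[tr]]
      use <- glab %in% lv & !is.na(v)
      if (length(lv) == 2) {
        pt <- pairwiseTests(v[use], glab[use], alpha)
        pw <- pt$p_value[pt$test == "wilcoxon"]
        ps <- pt$p_value[pt$test == "student_t"]
        pwe <- pt$p_value[pt$test == "welch_t"]
        sig <- c(pw, ps, pwe) <= alpha
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, grouping = g, n_groups = 2L, test = "pairwise",
          p_wilcoxon = pw, p_student = ps, p_welch = pwe,
          p_anova = NA_real_, letters = NA_character_,
          direction = pt$direction[1], significant = pw <= alpha,
          disagreement = length(unique(sig)) > 1,
          flag = pt$flag[1], stringsAsFactors = FALSE)
      } else {
        th <- tukeyHsd(v[use], glab[use], alpha)
        pa <- summary(aov(v[use] ~ factor(glab[use])))[[1]][1, "Pr(>F)"]
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, grouping = g, n_groups = length(lv), test = "tukey_hsd",
          p_wilcoxon = NA_real_, p_student = NA_real_, p_welch = NA_real_,
          p_anova = pa,
          letters = paste(paste0(names(th$letters), ":", th$letters),
                          collapse = ","),
          direction = NA_character_, significant = pa <= alpha,
          disagreement = FALSE, flag = th$flag, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(trait = character(0), grouping = character(0)))
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    pcol <- ifelse(is.na(out$p_wilcoxon), out$p_anova, out$p_wilcoxon)
    out$p_adjusted <- p.adjust(pcol, method = "BH")
    out$significant <- out$p_adjusted <= alpha
  }
  out
}
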