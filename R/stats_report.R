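# Statistical stage: unbalanced two-way ANOVA (group x inflow pattern)
# with Tukey HSD over the six cells and compact-letter display, plus
# Pearson correlations of the echo/IVPG variables against heart rate and
# the 1/2/3-coded inflow pattern. No multiplicity correction is applied
# across outcomes (matching the emulated analysis).

pattern_factor <- function(x) factor(x, levels = intersect(PATTERN_LEVELS, unique(x)))
group_factor <- function(x) factor(x, levels = intersect(c("Sham", "HTN-CM"), unique(x)))

#' Pearson correlation against heart rate or the coded inflow pattern
#'
#' Standard Pearson r between a cohort variable and either `hr` or the
#' ordinal pattern code (1 = EA-separation, 2 = EA-half-separation,
#' 3 = EA-fusion); p from the t transform with n - 2 degrees of freedom.
#' Rows with missing values in either column are dropped.
#'
#' @param tab cohort data.frame.
#' @param variable column name of the variable of interest.
#' @param against `"pattern_code"` (default) or `"hr"`.
#' @return list with `r`, `p`, `n`.
#' @export
cohort_pearson <- function(tab, variable, against = c("pattern_code", "hr")) {
  against <- match.arg(against)
  x <- tab[[variable]]
  if (is.null(x)) stop("no column `", variable, "`")
  y <- tab[[against]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete rows")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate variable: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-way ANOVA for a cohort outcome
#'
#' Fits `outcome ~ group * pattern` and reports per-term F and p.
#' Type-II sums of squares are the default for this unbalanced layout;
#' Type I (sequential) and Type III are available behind the `type`
#' flag. A cohort with a single group level drops the group factor with
#' a warning and reduces to a one-way ANOVA on pattern.
#'
#' @param tab cohort data.frame.
#' @param outcome outcome column name.
#' @param type sums-of-squares type: 2 (default), 1 or 3.
#' @return data.frame with columns `term`, `sum_sq`, `df`, `statistic`,
#'   `p`.
#' @export
two_way_anova <- function(tab, outcome, type = 2) {
  y <- tab[[outcome]]
  if (is.null(y)) stop("no column `", outcome, "`")
  d <- data.frame(y = y, group = group_factor(tab$group),
                  pattern = pattern_factor(tab$pattern))
  d <- d[stats::complete.cases(d), ]
  two_factor <- nlevels(d$group) >= 2
  if (!two_factor)
    warning("single group level; dropping the group factor")
  if (nlevels(d$pattern) < 2) stop("need at least 2 pattern levels")
  fml <- if (two_factor) y ~ group * pattern else y ~ pattern
  if (type == 3) {
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old))
  }
  fit <- stats::aov(fml, data = d)
  if (type == 1) {
    a <- stats::anova(fit)
    out <- data.frame(term = rownames(a), sum_sq = a$`Sum Sq`, df = a$Df,
                      statistic = a$`F value`, p = a$`Pr(>F)`)
  } else {
    a <- car::Anova(fit, type = type)
    out <- data.frame(term = rownames(a), sum_sq = a$`Sum Sq`, df = a$Df,
                      statistic = a$`F value`, p = a$`Pr(>F)`)
  }
  out$term <- trimws(out$term)
  rownames(out) <- NULL
  out
}

# split TukeyHSD rownames "A-B" into level pairs even when level names
# themselves contain hyphens (e.g. "HTN-CM:...")
split_pair <- function(rn, levels) {
  for (lv in levels[order(-nchar(levels))]) {
    pre <- paste0(lv, "-")
    if (startsWith(rn, pre)) {
      rest <- substring(rn, nchar(pre) + 1)
      if (rest %in% levels) return(c(lv, rest))
    }
  }
  stop("cannot parse Tukey contrast name: ", rn)
}

# insert-and-absorb compact letter display: start from one column holding
# every treatment; for each significantly different pair, duplicate every
# column containing both and delete one member from each copy; absorb
# columns that became subsets of another
cld_insert_absorb <- function(levels_desc, sig_pairs) {
  cols <- list(levels_desc)
  if (length(sig_pairs)) {
    for (k in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs[k, 1]; b <- sig_pairs[k, 2]
      new_cols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col)
          new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
        else new_cols <- c(new_cols, list(col))
      }
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i == j || !keep[i] || !keep[j]) next
          sub_ij <- all(new_cols[[i]] %in% new_cols[[j]])
          if (sub_ij && (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j))
            keep[i] <- FALSE
        }
      }
      cols <- new_cols[keep]
    }
  }
  ord <- order(vapply(cols, function(cl) min(match(cl, levels_desc)), 1))
  cols <- cols[ord]
  lett <- letters[seq_along(cols)]
  out <- vapply(levels_desc, function(lv)
    paste0(lett[vapply(cols, function(cl) lv %in% cl, TRUE)], collapse = ""),
    "")
  names(out) <- levels_desc
  out
}

#' Tukey HSD compact letters over the group x pattern cells
#'
#' Runs Tukey's HSD (studentized range, Tukey-Kramer for unequal cell
#' sizes) on the six group:pattern cell means of a one-way cell-means
#' fit, then summarizes the pairwise decisions at level `alpha` as a
#' compact letter display: cells sharing a letter are not significantly
#' different. Cells absent from the data simply drop their contrasts; a
#' warning flags cells with fewer than 2 observations.
#'
#' @param tab cohort data.frame.
#' @param outcome outcome column name.
#' @param alpha significance level (default 0.05).
#' @return list with `letters` (named by cell, ordered by decreasing
#'   mean), `pairwise` (data.frame `cell1`, `cell2`, `diff`, `p`),
#'   `means`, `n`.
#' @export
tukey_letters <- function(tab, outcome, alpha = 0.05) {
  y <- tab[[outcome]]
  if (is.null(y)) stop("no column `", outcome, "`")
  cell <- interaction(group_factor(tab$group), pattern_factor(tab$pattern),
                      sep = ":", lex.order = TRUE)
  d <- data.frame(y = y, cell = droplevels(cell))
  d <- d[stats::complete.cases(d), ]
  counts <- table(d$cell)
  if (sum(counts >= 2) < 2)
    stop("need at least 2 cells with at least 2 observations")
  if (any(counts < 2))
    warning("cell(s) with fewer than 2 observations: ",
            paste(names(counts)[counts < 2], collapse = ", "))
  fit <- stats::aov(y ~ cell, data = d)
  th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$cell
  levs <- levels(d$cell)
  pairs <- t(vapply(rownames(th), split_pair, character(2), levels = levs))
  pairwise <- data.frame(cell1 = pairs[, 1], cell2 = pairs[, 2],
                         diff = th[, "diff"], p = th[, "p adj"],
                         row.names = NULL)
  means <- tapply(d$y, d$cell, mean)
  desc <- names(sort(means, decreasing = TRUE))
  sig <- as.matrix(pairwise[pairwise$p < alpha, c("cell1", "cell2"), drop = FALSE])
  list(letters = cld_insert_absorb(desc, sig), pairwise = pairwise,
       means = means[desc], n = as.vector(counts[desc]))
}

DEFAULT_OUTCOMES <- c("lvm", "e", "hr", "eprime_avg", "e_over_eprime",
                      "lvedp", "prea_lvdp", "sap",
                      "total_ivpg", "basal_ivpg", "mid_apical_ivpg")
DEFAULT_CORR_VARS <- c("total_ivpg", "basal_ivpg", "mid_apical_ivpg",
                       "e_over_eprime", "e", "eprime_avg")

#' Full statistical report for a cohort
#'
#' Assembles, for each outcome, the two-way ANOVA table and the Tukey
#' compact letters over the six cells, renders a cell mean +/- SD table
#' with the letters, and computes Pearson correlations of the selected
#' variables against heart rate and the coded inflow pattern (plus HR
#' vs. pattern itself). Deterministic and invariant to row order.
#'
#' @param cohort a cohort data.frame or a path to a cohort CSV.
#' @param outcomes outcome columns for the ANOVA stage.
#' @param corr_vars variables for the correlation stage.
#' @param alpha significance level for the letter display.
#' @param anova_type sums-of-squares type passed to [two_way_anova()].
#' @return an object of class `stats_report`: `anova` (named list of
#'   data.frames), `tukey` (named list from [tukey_letters()]),
#'   `cell_table` (rendered mean +/- SD + letters), `pearson`
#'   (data.frame `variable`, `against`, `r`, `p`, `n`).
#' @export
run_full_analysis <- function(cohort, outcomes = DEFAULT_OUTCOMES,
                              corr_vars = DEFAULT_CORR_VARS,
                              alpha = 0.05, anova_type = 2) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  validate_cohort(cohort)
  outcomes <- intersect(outcomes, names(cohort))
  anova <- lapply(outcomes, function(o)
    two_way_anova(cohort, o, type = anova_type))
  names(anova) <- outcomes
  tukey <- lapply(outcomes, function(o) tukey_letters(cohort, o, alpha = alpha))
  names(tukey) <- outcomes
  cell <- interaction(group_factor(cohort$group),
                      pattern_factor(cohort$pattern), sep = ":",
                      lex.order = TRUE)
  cells <- levels(droplevels(cell))
  cell_table <- data.frame(outcome = outcomes, stringsAsFactors = FALSE)
  for (cl in cells) {
    cell_table[[cl]] <- vapply(outcomes, function(o) {
      y <- cohort[[o]][cell == cl]
      y <- y[is.finite(y)]
      lt <- tukey[[o]]$letters
      sprintf("%.2f ± %.2f %s", mean(y), stats::sd(y),
              if (cl %in% names(lt)) lt[[cl]] else "")
    }, "")
  }
  pe <- do.call(rbind, lapply(corr_vars, function(v) {
    do.call(rbind, lapply(c("hr", "pattern_code"), function(ag) {
      r <- cohort_pearson(cohort, v, against = ag)
      data.frame(variable = v, against = ag, r = r$r, p = r$p, n = r$n)
    }))
  }))
  hr_pat <- cohort_pearson(cohort, "hr", against = "pattern_code")
  pe <- rbind(pe, data.frame(variable = "hr", against = "pattern_code",
                             r = hr_pat$r, p = hr_pat$p, n = hr_pat$n))
  rownames(pe) <- NULL
  structure(list(anova = anova, tukey = tukey, cell_table = cell_table,
                 pearson = pe, alpha = alpha, anova_type = anova_type),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, digits = 3, ...) {
  cat("<stats_report> two-way ANOVA (type", x$anova_type,
      "SS) + Tukey letters + Pearson correlations\n\n")
  cat("Cell means ± SD (shared letter = not significantly different at alpha =",
      x$alpha, "):\n")
  print(x$cell_table, row.names = FALSE)
  cat("\nANOVA p-values:\n")
  pv <- do.call(rbind, lapply(names(x$anova), function(o) {
    a <- x$anova[[o]]
    a <- a[!a$term %in% c("Residuals", "(Intercept)"), ]
    data.frame(outcome = o,
               term = a$term, p = signif(a$p, digits))
  }))
  print(stats::reshape(pv, idvar = "outcome", timevar = "term",
                       direction = "wide"), row.names = FALSE)
  cat("\nPearson correlations:\n")
  pe <- x$pearson
  pe$r <- signif(pe$r, digits)
  pe$p <- signif(pe$p, digits)
  print(pe, row.names = FALSE)
  invisible(x)
}
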