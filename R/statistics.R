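MEASURE_VARS <- c("W", "H", "S", "kmax", "kmean", "ratio")

#' Coefficient of variation (percent)
#'
#' Sample (n-1) standard deviation over the mean, x 100.
#'
#' @param x numeric vector of length >= 2.
#' @return the CV in percent.
#' @export
cv_percent <- function(x) {
  if (length(x) < 2L) stop("CV needs at least 2 values")
  100 * stats::sd(x) / mean(x)
}

#' Per-species summary of tubercle records
#'
#' For each species (or other grouping label), returns the number of
#' tubercles and, per variable, the mean, coefficient of variation (sample
#' standard deviation / mean x 100), minimum and maximum — the layout of the
#' reference species tables.
#'
#' @param records data.frame of tubercle records (see [analyze_tubercle()]).
#' @param by name of the grouping column (default `"species"`).
#' @param variables measurement columns to summarize.
#' @return a data.frame with one row per group and columns `<var>_mean`,
#'   `<var>_cv`, `<var>_min`, `<var>_max`, plus `n_tubercles` (and
#'   `n_seeds`, `type`, `subgenus` when present in the input).
#' @export
summarize_species <- function(records, by = "species",
                              variables = intersect(MEASURE_VARS,
                                                    names(records))) {
  if (!by %in% names(records)) stop("no column '", by, "' in records")
  if (nrow(records) == 0L) stop("no records to summarize")
  groups <- split(records, records[[by]])
  if (any(vapply(groups, nrow, 1L) < 2L)) {
    stop("every group needs at least 2 records for the CV")
  }
  rows <- lapply(groups, function(g) {
    out <- data.frame(group = g[[by]][1L], n_tubercles = nrow(g))
    names(out)[1L] <- by
    if ("seed_id" %in% names(g)) {
      out$n_seeds <- length(unique(g$seed_id))
    }
    for (lab in c("type_label", "type", "subgenus")) {
      if (lab %in% names(g)) out[[sub("_label$", "", lab)]] <- g[[lab]][1L]
    }
    for (v in variables) {
      out[[paste0(v, "_mean")]] <- mean(g[[v]])
      out[[paste0(v, "_cv")]] <- cv_percent(g[[v]])
      out[[paste0(v, "_min")]] <- min(g[[v]])
      out[[paste0(v, "_max")]] <- max(g[[v]])
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classical one-way ANOVA from sums of squares
#'
#' The F statistic and p-value of the classical fixed-effects one-way
#' analysis of variance, computed directly from the between- and
#' within-group sums of squares.
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor), same length as `values`.
#' @return a list with `F`, `p`, `df` (numerator, denominator), `ss_between`
#'   and `ss_within`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  n_i <- tabulate(groups)
  if (any(n_i < 2L)) stop("every group needs at least 2 values")
  m_i <- tapply(values, groups, mean)
  gm <- mean(values)
  ss_b <- sum(n_i * (m_i - gm)^2)
  ss_w <- sum((values - m_i[groups])^2)
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  if (ss_w == 0 && ss_b == 0) {
    return(list(F = 0, p = 1, df = c(df1, df2), ss_between = 0, ss_within = 0))
  }
  F <- (ss_b / df1) / (ss_w / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), ss_between = ss_b, ss_within = ss_w)
}

#' Tukey honest significant differences
#'
#' All pairwise group comparisons with the studentized-range distribution;
#' unbalanced designs use the Tukey-Kramer standard error.
#'
#' @param values numeric response vector.
#' @param groups group labels.
#' @param alpha family-wise significance level.
#' @return a data.frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean of group2 minus group1), `p` and `significant`, plus attribute
#'   `alpha`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  an <- anova_oneway(values, groups)
  lev <- levels(groups)
  n_i <- tabulate(groups)
  m_i <- tapply(values, groups, mean)
  mse <- an$ss_within / an$df[2]
  pairs <- utils::combn(seq_along(lev), 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(mse / 2 * (1 / n_i[i] + 1 / n_i[j]))
    q <- abs(m_i[j] - m_i[i]) / se
    p <- stats::ptukey(q, nmeans = length(lev), df = an$df[2],
                       lower.tail = FALSE)
    data.frame(group1 = lev[i], group2 = lev[j],
               diff = unname(m_i[j] - m_i[i]), p = p)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  attr(out, "alpha") <- alpha
  attr(out, "means") <- m_i
  out
}

#' Compact letter display
#'
#' Assigns letters to groups such that two groups share a letter if and only
#' if they are not significantly different, using the insert-and-absorb
#' algorithm. Letters are issued in increasing order of group mean (smallest
#' mean gets "a"); ties are broken alphabetically by group name.
#'
#' @param pairwise either the data.frame returned by [tukey_hsd()] or a
#'   symmetric logical matrix of significance decisions with group names.
#' @param means optional named vector of group means used to order the
#'   letters (taken from the `tukey_hsd` attribute when available).
#' @return named character vector of letter codes.
#' @examples
#' m <- matrix(FALSE, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' m["A", "C"] <- m["C", "A"] <- TRUE
#' compact_letter_display(m, means = c(A = 1, B = 2, C = 3))
#' @export
compact_letter_display <- function(pairwise, means = NULL) {
  if (is.data.frame(pairwise)) {
    lev <- sort(unique(c(pairwise$group1, pairwise$group2)))
    sig <- matrix(FALSE, length(lev), length(lev),
                  dimnames = list(lev, lev))
    for (r in seq_len(nrow(pairwise))) {
      if (pairwise$significant[r]) {
        sig[pairwise$group1[r], pairwise$group2[r]] <- TRUE
        sig[pairwise$group2[r], pairwise$group1[r]] <- TRUE
      }
    }
    if (is.null(means)) means <- attr(pairwise, "means")
  } else {
    sig <- pairwise
    if (!isTRUE(all.equal(sig, t(sig)))) stop("decision matrix must be symmetric")
    lev <- rownames(sig)
  }
  if (is.null(means)) means <- stats::setNames(rep(0, length(lev)), lev)
  ord <- lev[order(means[lev], lev)]
  sig <- sig[ord, ord, drop = FALSE]
  k <- length(ord)
  # insert-and-absorb: columns are letter classes (logical membership)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i || !sig[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] <= cols[[cj]]) && !identical(cols[[ci]], cols[[cj]])) {
        keep[ci] <- FALSE
      }
    }
    dup <- duplicated(cols) & keep
    cols <- cols[keep & !dup]
  }
  # order letter classes by the first (smallest-mean) member they contain
  first <- vapply(cols, function(col) which(col)[1L], 1L)
  cols <- cols[order(first)]
  letts <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(col) col[i], TRUE))],
          collapse = "")
  }, character(1))
  stats::setNames(letts, ord)[lev]
}

#' Pooled group comparison of tubercle records
#'
#' Pools records by a grouping label (seed type or subgenus), summarizing
#' each group (mean, CV, min, max per variable) and comparing groups by
#' one-way ANOVA with Tukey letters — the layout of the pooled reference
#' tables.
#'
#' @param records data.frame of tubercle records; every record must carry a
#'   non-missing group label.
#' @param grouping name of the grouping column.
#' @param variables measurement columns to compare.
#' @param alpha significance level for the letters.
#' @return a list with `summary` (data.frame, one row per group; per
#'   variable mean/cv/min/max and `<var>_letter`), and `tests` (per variable
#'   the `anova_oneway()` result).
#' @export
pooled_group_stats <- function(records, grouping,
                               variables = intersect(MEASURE_VARS,
                                                     names(records)),
                               alpha = 0.05) {
  if (!grouping %in% names(records)) {
    stop("no column '", grouping, "' in records")
  }
  if (anyNA(records[[grouping]])) stop("unlabeled records present")
  summ <- summarize_species(records, by = grouping, variables = variables)
  tests <- list()
  single <- length(unique(records[[grouping]])) < 2L
  for (v in variables) {
    if (single) break
    tests[[v]] <- anova_oneway(records[[v]], records[[grouping]])
    tk <- tukey_hsd(records[[v]], records[[grouping]], alpha = alpha)
    letts <- compact_letter_display(tk)
    summ[[paste0(v, "_letter")]] <- unname(letts[summ[[grouping]]])
  }
  list(summary = summ, tests = tests)
}

#' Tubercle-count-weighted group means from per-species summaries
#'
#' Pools per-species summary rows into group-level means, weighting each
#' species mean by its tubercle count `N`. Pooled means computed this way
#' agree with pooled means over the raw records whenever the species means
#' themselves do.
#'
#' @param summaries data.frame in the layout of [summarize_species()] /
#'   [silene_species_summaries()], with `n_tubercles` and `<var>_mean`
#'   columns.
#' @param by grouping column in `summaries` (e.g. `"type"`, `"subgenus"`).
#' @param variables base variable names.
#' @return a data.frame with one row per group: `n_tubercles` and the
#'   weighted `<var>_mean` columns, plus `<var>_min`/`<var>_max` pooled over
#'   species when present.
#' @export
weighted_group_means <- function(summaries, by = "type",
                                 variables = MEASURE_VARS) {
  if (!by %in% names(summaries)) stop("no column '", by, "' in summaries")
  groups <- split(summaries, summaries[[by]])
  rows <- lapply(groups, function(g) {
    out <- data.frame(group = g[[by]][1L], n_tubercles = sum(g$n_tubercles))
    names(out)[1L] <- by
    for (v in variables) {
      mv <- paste0(v, "_mean")
      if (!mv %in% names(g)) stop("missing column ", mv)
      out[[mv]] <- sum(g$n_tubercles * g[[mv]]) / sum(g$n_tubercles)
      for (s in c("min", "max")) {
        cn <- paste0(v, "_", s)
        if (cn %in% names(g)) {
          out[[cn]] <- if (s == "min") min(g[[cn]]) else max(g[[cn]])
        }
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
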