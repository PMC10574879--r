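#' Build the species x variables feature matrix
#'
#' Assembles per-species trait means into the matrix clustered by
#' [ward_dendrogram()]. The default variable set is the six measurement
#' means; a single-variable matrix (e.g. maximum curvature only) is equally
#' valid. Optional per-column standardization (z-scores) is off by default.
#'
#' @param summaries data.frame of per-species summaries (layout of
#'   [summarize_species()] or [silene_species_summaries()]).
#' @param variables base variable names; `<var>_mean` columns must exist.
#' @param standardize logical; scale columns to zero mean, unit variance.
#' @return a numeric matrix with species row names; attribute `subgenus`
#'   (and `type`) carried over when present.
#' @export
build_feature_matrix <- function(summaries,
                                 variables = MEASURE_VARS,
                                 standardize = FALSE) {
  if (length(variables) == 0L) stop("empty variable selection")
  if (nrow(summaries) < 2L) stop("need at least 2 species")
  cols <- paste0(variables, "_mean")
  missing_cols <- setdiff(cols, names(summaries))
  if (length(missing_cols)) {
    stop("missing variable column(s): ", paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(summaries[, cols, drop = FALSE])
  colnames(m) <- variables
  rownames(m) <- summaries$species
  bad <- rownames(m)[!stats::complete.cases(m)]
  if (length(bad)) {
    stop("missing values for species: ", paste(bad, collapse = ", "))
  }
  if (standardize) m <- scale(m)
  for (lab in c("subgenus", "type")) {
    if (lab %in% names(summaries)) {
      attr(m, lab) <- stats::setNames(summaries[[lab]], summaries$species)
    }
  }
  m
}

#' Ward hierarchical clustering of species trait means
#'
#' Agglomerative clustering with Euclidean distances under Ward's
#' minimum-variance criterion (the `ward.D2` formulation: squared distances
#' in the Lance-Williams update, merge heights on the distance scale). The
#' merge sequence is deterministic given the matrix.
#'
#' @param m feature matrix from [build_feature_matrix()] (>= 2 rows).
#' @return an `"hclust"` object; label attributes of `m` are carried over.
#' @export
ward_dendrogram <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  for (lab in c("subgenus", "type")) {
    if (!is.null(attr(m, lab))) attr(hc, lab) <- attr(m, lab)
  }
  hc
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are merge-height differences, so each leaf's root depth
#' equals the final merge height (an ultrametric tree). Two leaves merged at
#' height h yield `"(A:h,B:h);"`.
#'
#' @param tree an `"hclust"` from [ward_dendrogram()].
#' @param labels leaf labels (default: the tree's labels); length must match.
#' @param file optional path to write the string to.
#' @return the Newick string, invisibly when `file` is given.
#' @export
export_newick <- function(tree, labels = tree$labels, file = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (length(labels) != n) {
    stop("label count (", length(labels), ") does not match leaf count (",
         n, ")")
  }
  node <- function(i, parent_height) {
    if (i < 0) { # leaf (hclust merge convention: negatives are observations)
      sprintf("%s:%.10g", gsub("[(),:;[:space:]]", "_", labels[-i]),
              parent_height)
    } else {
      h <- tree$height[i]
      sprintf("(%s,%s):%.10g",
              node(tree$merge[i, 1], h), node(tree$merge[i, 2], h),
              parent_height - h)
    }
  }
  top <- n - 1L
  h <- tree$height[top]
  nwk <- sprintf("(%s,%s);", node(tree$merge[top, 1], h),
                 node(tree$merge[top, 2], h))
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}

#' Plot a species dendrogram with subgenus-colored labels
#'
#' @param tree an `"hclust"`, typically carrying a `subgenus` attribute
#'   (from [ward_dendrogram()] on an annotated matrix).
#' @param subgenus optional named vector of subgenus labels per species.
#' @param colors named color vector keyed by subgenus.
#' @param ... passed to `plot.dendrogram()`.
#' @return the colored `"dendrogram"`, invisibly.
#' @export
plot_dendrogram <- function(tree, subgenus = attr(tree, "subgenus"),
                            colors = c(Behenantha = "red", Silene = "blue"),
                            ...) {
  dend <- stats::as.dendrogram(tree)
  if (!is.null(subgenus)) {
    dend <- stats::dendrapply(dend, function(n) {
      if (is.leaf(n)) {
        lab <- attr(n, "label")
        col <- colors[subgenus[lab]]
        if (!is.na(col)) {
          attr(n, "nodePar") <- c(attr(n, "nodePar"),
                                  list(lab.col = unname(col), pch = NA))
        }
      }
      n
    })
  }
  plot(dend, ylab = "Ward merge height", ...)
  invisible(dend)
}

#' Linkage table of an hclust tree
#'
#' @param tree an `"hclust"`.
#' @return data.frame with columns `merge1`, `merge2`, `height`.
#' @export
linkage_table <- function(tree) {
  data.frame(merge1 = tree$merge[, 1], merge2 = tree$merge[, 2],
             height = tree$height)
}
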