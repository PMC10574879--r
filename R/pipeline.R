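#' Validated run configuration
#'
#' Collects the tunable parameters of the end-to-end pipeline, validating
#' them up front. The configuration is serialized into every output
#' manifest so each result directory records how it was produced.
#'
#' @param bezier_degree Bezier degree (>= 2) or `"auto"`.
#' @param n_curvature_samples curvature samples per tubercle (>= 50).
#' @param threshold `"otsu"` or a gray level in `[0, 255]`.
#' @param smooth_window odd moving-average window (px); 0 disables.
#' @param alpha significance level in (0, 1).
#' @param cluster_variables variable subset used for clustering.
#' @param seed integer RNG seed or `NULL`.
#' @param quiet suppress per-tubercle progress messages.
#' @return a validated list of class `"run_config"`.
#' @export
run_config <- function(bezier_degree = 5, n_curvature_samples = 200,
                       threshold = "otsu", smooth_window = 3, alpha = 0.05,
                       cluster_variables = MEASURE_VARS,
                       seed = NULL, quiet = FALSE) {
  if (!identical(bezier_degree, "auto") &&
      (!is.numeric(bezier_degree) || bezier_degree < 2)) {
    stop("bezier_degree must be >= 2 or \"auto\"")
  }
  if (n_curvature_samples < 50) stop("n_curvature_samples must be >= 50")
  if (!identical(threshold, "otsu") &&
      (!is.numeric(threshold) || threshold < 0 || threshold > 255)) {
    stop("threshold must be \"otsu\" or in [0, 255]")
  }
  if (smooth_window != 0 && smooth_window %% 2 != 1) {
    stop("smooth_window must be odd or 0")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!all(cluster_variables %in% MEASURE_VARS)) {
    stop("unknown cluster variable(s): ",
         paste(setdiff(cluster_variables, MEASURE_VARS), collapse = ", "))
  }
  structure(list(bezier_degree = bezier_degree,
                 n_curvature_samples = n_curvature_samples,
                 threshold = threshold, smooth_window = smooth_window,
                 alpha = alpha, cluster_variables = cluster_variables,
                 seed = seed, quiet = quiet),
            class = "run_config")
}

pipeline_log <- function(config, ...) {
  if (!isTRUE(config$quiet)) message(...)
}

#' Write a run manifest
#'
#' Records the configuration, package version and MD5 checksums of the
#' inputs alongside the outputs of a pipeline stage.
#'
#' @param dir output directory.
#' @param config a [run_config()].
#' @param inputs character vector of input file paths (hashed if they
#'   exist).
#' @param outputs character vector of produced files.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, inputs = character(),
                           outputs = character()) {
  existing <- inputs[file.exists(inputs)]
  manifest <- list(
    package = "tubermorph",
    version = as.character(utils::packageVersion("tubermorph")),
    config = unclass(config),
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(existing)), basename(existing))),
    outputs = basename(outputs)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Extract tubercle coordinate files from seed images
#'
#' Batch front end to the extraction stage: each image is read, thresholded,
#' its largest outline traced and converted to a line-graph profile, and the
#' profile written as a coordinate CSV next to a run manifest. Failing
#' images are logged and skipped; the function errors at the end if any
#' failed.
#'
#' @param paths image file paths.
#' @param microns_per_pixel calibration factor (scalar, or one per image).
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @return data.frame with columns `image`, `csv`, `ok`.
#' @export
process_images <- function(paths, microns_per_pixel, out_dir = ".",
                           config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mpp <- rep_len(microns_per_pixel, length(paths))
  res <- lapply(seq_along(paths), function(i) {
    csv <- file.path(out_dir,
                     paste0(sub("\\.[^.]+$", "", basename(paths[i])), ".csv"))
    ok <- tryCatch({
      img <- read_seed_image(paths[i], mpp[i])
      mask <- binarize(img, config$threshold)
      seg <- trace_outline(mask)[[1L]]
      prof <- extract_profile(seg, mpp[i],
                              smooth_window = config$smooth_window)
      write_profile_csv(prof, csv)
      pipeline_log(config, "extracted ", basename(paths[i]), " -> ",
                   basename(csv))
      TRUE
    }, error = function(e) {
      pipeline_log(config, "FAILED ", basename(paths[i]), ": ",
                   conditionMessage(e))
      FALSE
    })
    data.frame(image = paths[i], csv = ifelse(ok, csv, NA_character_),
               ok = ok)
  })
  res <- do.call(rbind, res)
  write_manifest(out_dir, config, inputs = paths,
                 outputs = stats::na.omit(res$csv))
  if (!all(res$ok)) {
    stop(sum(!res$ok), " image(s) failed; see log and manifest in ", out_dir)
  }
  res
}

#' Measure tubercle records from coordinate files
#'
#' Runs [analyze_tubercle()] over a set of coordinate CSVs (layout of
#' [write_profile_csv()]), joining provenance labels by file name, and
#' writes the per-tubercle table.
#'
#' @param csv_paths coordinate CSV paths.
#' @param labels optional data.frame with a `file` column (base names
#'   matching `csv_paths`) plus any of `species`, `seed_id`, `tubercle_no`,
#'   `type`, `subgenus`.
#' @param out optional output CSV path for the measured table.
#' @param config a [run_config()].
#' @return the per-tubercle records data.frame.
#' @export
measure_profiles <- function(csv_paths, labels = NULL, out = NULL,
                             config = run_config()) {
  if (length(csv_paths) == 0L) stop("no coordinate files given")
  rows <- lapply(csv_paths, function(p) {
    prof <- read_profile_csv(p)
    lab <- list(species = NA_character_, seed_id = NA_character_,
                tubercle_no = NA_integer_, type = NA_character_,
                subgenus = NA_character_)
    if (!is.null(labels)) {
      hit <- labels[labels$file == basename(p), , drop = FALSE]
      if (nrow(hit) == 1L) {
        for (f in intersect(names(lab), names(hit))) lab[[f]] <- hit[[f]][1L]
      }
    }
    rec <- analyze_tubercle(prof, degree = config$bezier_degree,
                            n_samples = config$n_curvature_samples,
                            smooth_window = config$smooth_window,
                            species = lab$species, seed_id = lab$seed_id,
                            tubercle_no = lab$tubercle_no,
                            type_label = lab$type, subgenus = lab$subgenus)
    pipeline_log(config, "measured ", basename(p))
    rec
  })
  records <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.csv(format_records(records), out, row.names = FALSE)
    write_manifest(dirname(out), config, inputs = csv_paths, outputs = out)
  }
  records
}

# fixed-precision formatting keeps repeated runs byte-identical
format_records <- function(records) {
  num <- vapply(records, is.numeric, TRUE)
  records[num] <- lapply(records[num], function(x) sprintf("%.6f", x))
  records
}

#' Summary and comparison reports from a per-tubercle table
#'
#' Produces the per-species summary and, when a grouping column is given,
#' the pooled group comparison (ANOVA + Tukey letters), optionally writing
#' both as CSV and a Markdown report in the mean (CV) / min-max layout of
#' the reference tables.
#'
#' @param records per-tubercle records (data.frame or CSV path).
#' @param grouping optional grouping column (e.g. `"type_label"`).
#' @param out_dir optional output directory.
#' @param config a [run_config()].
#' @return list with `species` (summary data.frame) and, if grouped,
#'   `comparison` (see [pooled_group_stats()]).
#' @export
stats_report <- function(records, grouping = NULL, out_dir = NULL,
                         config = run_config()) {
  if (is.character(records)) records <- utils::read.csv(records)
  if (nrow(records) == 0L) stop("empty records table")
  out <- list(species = summarize_species(records))
  if (!is.null(grouping)) {
    out$comparison <- pooled_group_stats(records, grouping,
                                         alpha = config$alpha)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(out_dir, "species_summary.csv")
    utils::write.csv(format_records(out$species), f1, row.names = FALSE)
    files <- f1
    if (!is.null(grouping)) {
      f2 <- file.path(out_dir, "group_comparison.csv")
      utils::write.csv(format_records(out$comparison$summary), f2,
                       row.names = FALSE)
      f3 <- file.path(out_dir, "group_comparison.md")
      writeLines(markdown_report(out$comparison$summary, grouping), f3)
      files <- c(files, f2, f3)
    }
    write_manifest(out_dir, config, outputs = files)
  }
  out
}

markdown_report <- function(summ, grouping) {
  vars <- MEASURE_VARS[paste0(MEASURE_VARS, "_mean") %in% names(summ)]
  header <- paste0("| ", grouping, " | N | ",
                   paste(vars, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(vars) + 2), collapse = "|"), "|")
  rows <- vapply(seq_len(nrow(summ)), function(i) {
    cells <- vapply(vars, function(v) {
      lett <- summ[[paste0(v, "_letter")]]
      sprintf("%.1f^%s^ (%.1f) %.1f/%.1f",
              summ[[paste0(v, "_mean")]][i],
              if (is.null(lett)) "" else lett[i],
              summ[[paste0(v, "_cv")]][i],
              summ[[paste0(v, "_min")]][i], summ[[paste0(v, "_max")]][i])
    }, character(1))
    paste0("| ", summ[[grouping]][i], " | ", summ$n_tubercles[i], " | ",
           paste(cells, collapse = " | "), " |")
  }, character(1))
  c(header, sep, rows)
}

#' Cluster species summaries and export the dendrogram
#'
#' @param summaries per-species summary (data.frame or CSV path).
#' @param out_dir optional output directory for `tree.nwk`, `linkage.csv`
#'   and `dendrogram.svg`.
#' @param standardize passed to [build_feature_matrix()].
#' @param config a [run_config()].
#' @return the `"hclust"` tree, invisibly.
#' @export
cluster_species <- function(summaries, out_dir = NULL, standardize = FALSE,
                            config = run_config()) {
  if (is.character(summaries)) summaries <- utils::read.csv(summaries)
  m <- build_feature_matrix(summaries, variables = config$cluster_variables,
                            standardize = standardize)
  tree <- ward_dendrogram(m)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    nwk <- file.path(out_dir, "tree.nwk")
    export_newick(tree, file = nwk)
    lk <- file.path(out_dir, "linkage.csv")
    utils::write.csv(format_records(linkage_table(tree)), lk,
                     row.names = FALSE)
    sv <- file.path(out_dir, "dendrogram.svg")
    grDevices::svg(sv, width = 8, height = 6)
    plot_dendrogram(tree)
    grDevices::dev.off()
    write_manifest(out_dir, config, outputs = c(nwk, lk, sv))
  }
  invisible(tree)
}
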