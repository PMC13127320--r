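#' Read and write analysis tables as CSV
#'
#' Plain-CSV round-trip for the package's tabular outputs (segment records,
#' schedules, comparisons, reports); `read_table()` returns a tibble.
#'
#' @param df A data frame.
#' @param path File path.
#' @return `write_table()` returns `path` invisibly; `read_table()` a tibble.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a segment-record table with validation
#'
#' Reads the CSV and checks the measurement columns are numeric and
#' complete; a malformed cell yields a parse error naming the row and
#' column.
#'
#' @param path CSV file path.
#' @return A validated tibble of segment records.
#' @export
read_segment_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  num_cols <- intersect(
    c("mda_gt_unadjusted", "dmda_gt_unadjusted", "mda_gt_adjusted",
      "dmda_gt_adjusted", "inter_algo_mda", "area_cm2"),
    names(df))
  for (cl in num_cols) {
    suppressWarnings(v <- as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !(df[[cl]] %in% c("", "NA")))
    if (length(bad) > 0L) {
      abort_domain(sprintf("parse error in %s: column '%s', row %d ('%s') is not numeric",
                           basename(path), cl, bad[1], df[[cl]][bad[1]]))
    }
    df[[cl]] <- v
  }
  for (cl in intersect(c("session", "order_in_session"), names(df))) {
    df[[cl]] <- as.integer(df[[cl]])
  }
  tibble::as_tibble(df)
}

# write the study outputs + manifest under out_dir; returns the manifest
write_study <- function(study, cases, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  files <- character(0)
  for (case in cases) {
    for (nm in c("ctv1", "ground_truth")) {
      f <- file.path(mask_dir, sprintf("%s_%s.nii.gz", case$case_id, nm))
      write_mask(case[[nm]], f)
      files <- c(files, f)
    }
    for (alg in names(case$ctv2)) {
      f <- file.path(mask_dir, sprintf("%s_ctv2_%s.nii.gz", case$case_id, alg))
      write_mask(case$ctv2[[alg]], f)
      files <- c(files, f)
    }
  }
  tabs <- c(records = "records.csv", schedule = "schedule.csv",
            screening = "screening.csv", sites = "sites.csv")
  for (nm in names(tabs)) {
    f <- file.path(out_dir, tabs[nm])
    write_table(as.data.frame(study[[nm]]), f)
    files <- c(files, f)
  }
  cfg_path <- file.path(out_dir, "config.json")
  cfg <- study$config
  cfg$profiles <- as.data.frame(cfg$profiles)
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, cfg_path)
  manifest <- list(
    seed = study$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("adaptbias")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Primary-endpoint report of a study
#'
#' Assembles the headline analysis from a segment-record table: the
#' pairwise comparisons of the two deformable arms, the positive-comparison
#' proportions with exact confidence intervals and the exact binomial
#' superiority test, overall and split at the median inter-algorithm
#' deviation, plus the larger-adjustment endpoint.
#'
#' @param records A segment-record tibble (from [generate_study()],
#'   [simulate_records()], or [read_segment_records()]).
#' @param conf_level Confidence level of the exact intervals.
#' @return A list with `comparisons`, `table1` (the proportion table), and
#'   `larger_adjustment` (one-row tibble).
#' @export
study_report <- function(records, conf_level = 0.95) {
  cmp <- build_pairwise_comparisons(records)
  tab <- summarize_comparisons(cmp, conf_level = conf_level)
  k <- sum(cmp$larger_adjustment_on_worse)
  n <- nrow(cmp)
  larger <- tibble::tibble(
    endpoint = "larger adjustment on worse arm",
    positives = k, n = n, proportion = k / n,
    p_exact = exact_binomial_test(k, n, p0 = 0.5, direction = "greater")
  )
  list(comparisons = cmp, table1 = tab, larger_adjustment = larger)
}

#' Plot a primary-endpoint proportion table
#'
#' Point-and-interval display of the positive-comparison proportions from
#' [summarize_comparisons()] with the null 0.5 and alternative 0.65
#' proportions as reference lines.
#'
#' @param table1 Output of [summarize_comparisons()].
#' @param p0,p1 Reference proportions.
#' @return A ggplot object.
#' @export
plot_comparison_summary <- function(table1, p0 = 0.5, p1 = 0.65) {
  ggplot2::ggplot(table1, ggplot2::aes(x = .data$subgroup, y = .data$proportion)) +
    ggplot2::geom_hline(yintercept = p0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = p1, linetype = "dotted", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proportion of positive pairwise comparisons") +
    ggplot2::theme_minimal()
}
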