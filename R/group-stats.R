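#' Tally localization classes
#'
#' Counts direct / AcD / multi cells per group from a measurement or truth
#' table. Undetermined cells still carry their localization annotation and
#' are counted (localization is a per-neuron annotation, independent of
#' whether the bounds could be measured).
#'
#' @param measurements Tibble with a `localization_class` column and,
#'   optionally, `group_label`.
#' @return Tibble with columns `group_label`, `n_direct`, `n_acd`,
#'   `n_multi`.
#' @export
count_localizations <- function(measurements) {
  if (!"group_label" %in% names(measurements)) measurements$group_label <- "all"
  measurements |>
    dplyr::distinct(.data$group_label, .data$neuron_id, .data$localization_class) |>
    dplyr::count(.data$group_label, .data$localization_class) |>
    tidyr::pivot_wider(names_from = "localization_class", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      for (cl in LOCALIZATION_CLASSES) if (!cl %in% names(d)) d[[cl]] <- 0L
      d
    })() |>
    dplyr::transmute(.data$group_label,
                     n_direct = .data$direct, n_acd = .data$acd,
                     n_multi = .data$multi)
}

#' Localization proportions
#'
#' Converts per-group counts into percentages of the group total. The
#' reporting precision follows the convention used for the source cohorts:
#' rounded to the nearest integer when the group total is below 200 cells
#' and to one decimal otherwise; the raw unrounded proportions are always
#' kept alongside.
#'
#' @param counts Tibble with columns `n_direct`, `n_acd`, `n_multi` and,
#'   optionally, `group_label` (see [count_localizations()]).
#' @return Tibble with the counts, the total, raw percentages
#'   (`raw_pct_*`) and display-rounded percentages (`pct_*`).
#' @export
#' @examples
#' localization_proportions(tibble::tibble(n_direct = 131, n_acd = 4, n_multi = 0))
localization_proportions <- function(counts) {
  need <- c("n_direct", "n_acd", "n_multi")
  if (!all(need %in% names(counts))) {
    abort("`counts` needs columns n_direct, n_acd, n_multi.")
  }
  if (!"group_label" %in% names(counts)) counts$group_label <- "all"
  total <- counts$n_direct + counts$n_acd + counts$n_multi
  if (any(total <= 0)) abort("Localization totals must be positive.")
  digits <- ifelse(total < 200, 0L, 1L)
  out <- counts |>
    dplyr::mutate(
      total = total,
      raw_pct_direct = 100 * .data$n_direct / total,
      raw_pct_acd = 100 * .data$n_acd / total,
      raw_pct_multi = 100 * .data$n_multi / total,
      pct_direct = round(.data$raw_pct_direct, digits),
      pct_acd = round(.data$raw_pct_acd, digits),
      pct_multi = round(.data$raw_pct_multi, digits)
    )
  as_tibble(out)
}

#' Grubbs single-outlier test
#'
#' Two-sided Grubbs test: `G = max |x - mean| / sd`, compared with the
#' critical value `((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` where
#' `t` is the upper `alpha / (2n)` Student-t quantile on `n - 2` degrees of
#' freedom. At most one value is flagged per call (single-outlier variant,
#' matching one screening pass per comparison group).
#'
#' @param values Numeric vector, `n >= 3`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `grubbs_test` with fields `statistic`,
#'   `critical`, `flagged`, `outlier_index`, `outlier_value`, `alpha`, `n`.
#'   All-equal input flags nothing (with a warning).
#' @export
#' @examples
#' grubbs_test(c(1, 2, 3, 4, 100))
grubbs_test <- function(values, alpha = 0.05) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3) abort("Grubbs test requires n >= 3 values.")
  if (any(!is.finite(x))) abort("`values` must be finite.")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  s <- sd(x)
  if (s == 0) {
    warn("Zero variance: no outlier can be flagged.")
    res <- list(statistic = 0, critical = Inf, flagged = FALSE,
                outlier_index = NA_integer_, outlier_value = NA_real_,
                alpha = alpha, n = n)
    return(structure(res, class = "grubbs_test"))
  }
  dev <- abs(x - mean(x))
  idx <- which.max(dev)
  g <- dev[idx] / s
  tq <- qt(1 - alpha / (2 * n), df = n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  flagged <- g > crit
  res <- list(
    statistic = g, critical = crit, flagged = flagged,
    outlier_index = if (flagged) idx else NA_integer_,
    outlier_value = if (flagged) x[idx] else NA_real_,
    alpha = alpha, n = n
  )
  structure(res, class = "grubbs_test")
}

#' Chi-square test of homogeneity for localization distributions
#'
#' Pearson chi-square on a groups-by-classes contingency table with expected
#' counts `row_i * col_j / N`. Classes absent from every group (zero grand
#' total) are dropped and the degrees of freedom reduced accordingly; a
#' group with zero total is an error. Computation is delegated to
#' [stats::chisq.test()] without continuity correction.
#'
#' @param table Matrix, data frame or tibble; rows = groups, columns =
#'   localization classes. A `group_label` column, if present, is used for
#'   row names.
#' @return An object of class `chisq_homogeneity` with `statistic`, `df`,
#'   `p_value`, `observed`, `expected`, `dropped_columns`.
#' @export
chi_square_homogeneity <- function(table) {
  tab <- table
  if (is.data.frame(tab)) {
    labels <- if ("group_label" %in% names(tab)) tab$group_label else rownames(tab)
    tab <- as.matrix(tab[setdiff(names(tab), "group_label")])
    rownames(tab) <- labels
  }
  tab <- as.matrix(tab)
  storage.mode(tab) <- "double"
  if (nrow(tab) < 2) abort("At least 2 groups are required.")
  if (any(tab < 0)) abort("Counts must be non-negative.")
  row_tot <- rowSums(tab)
  if (any(row_tot == 0)) abort("Every group must have a positive total.")
  dropped <- colnames(tab)[colSums(tab) == 0] %||% character()
  keep <- colSums(tab) > 0
  tab_kept <- tab[, keep, drop = FALSE]
  if (ncol(tab_kept) < 2) {
    abort("At least 2 classes with non-zero totals are required.")
  }
  ht <- suppressWarnings(stats::chisq.test(tab_kept, correct = FALSE))
  res <- list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    observed = tab_kept,
    expected = ht$expected,
    dropped_columns = if (length(dropped)) dropped else character()
  )
  structure(res, class = "chisq_homogeneity")
}

#' Replicate-level AIS dimension summaries with exclusion rules
#'
#' Applies the dimension-analysis exclusions in order: (1) cells whose
#' bounds are `undetermined` (weak labeling), (2) `multi` cells (no primary
#' axon can be assigned), (3) replicates contributing fewer than
#' `min_ais_per_device` determined AISs of a localization type (the
#' "too few identifiable AISs" device rule). Remaining cells are averaged
#' within each replicate, and group-level statistics are computed over the
#' replicate means — replicates, not cells, are the unit of analysis.
#'
#' @param measurements Measurement tibble (schema of [quantify_ais()]) with
#'   additional `replicate_id` and, optionally, `group_label` columns.
#' @param min_ais_per_device Minimum determined AISs per replicate x
#'   localization for the replicate to count (default 3).
#' @return An object of class `dimension_summary`: a list with tibbles
#'   `replicate_means`, `group_means` and `exclusions`.
#' @export
summarize_dimensions <- function(measurements, min_ais_per_device = 3) {
  need <- c("replicate_id", "localization_class", "status",
            "start_um", "length_um")
  if (!all(need %in% names(measurements))) {
    abort(paste0("`measurements` needs columns: ", paste(need, collapse = ", "), "."))
  }
  m <- as_tibble(measurements)
  if (!"group_label" %in% names(m)) m$group_label <- "all"

  n_seen <- m |> dplyr::count(.data$group_label, name = "n_seen")
  undet <- m |> dplyr::filter(.data$status != "determined")
  m1 <- m |> dplyr::filter(.data$status == "determined")
  multi <- m1 |> dplyr::filter(.data$localization_class == "multi")
  m2 <- m1 |> dplyr::filter(.data$localization_class != "multi")

  rep_counts <- m2 |>
    dplyr::count(.data$group_label, .data$localization_class, .data$replicate_id)
  small <- rep_counts |> dplyr::filter(.data$n < min_ais_per_device)
  m3 <- m2 |>
    dplyr::anti_join(small, by = c("group_label", "localization_class", "replicate_id"))

  replicate_means <- m3 |>
    dplyr::group_by(.data$group_label, .data$localization_class, .data$replicate_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_start_um = mean(.data$start_um),
      mean_length_um = mean(.data$length_um),
      .groups = "drop"
    )
  group_means <- replicate_means |>
    dplyr::group_by(.data$group_label, .data$localization_class) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_cells = sum(.data$n_cells),
      mean_start_um = mean(.data$mean_start_um),
      sem_start_um = sd(.data$mean_start_um) / sqrt(dplyr::n()),
      mean_length_um = mean(.data$mean_length_um),
      sem_length_um = sd(.data$mean_length_um) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  exclusions <- n_seen |>
    dplyr::left_join(
      undet |> dplyr::count(.data$group_label, name = "n_excluded_undetermined"),
      by = "group_label"
    ) |>
    dplyr::left_join(
      multi |> dplyr::count(.data$group_label, name = "n_excluded_multi"),
      by = "group_label"
    ) |>
    dplyr::left_join(
      m2 |>
        dplyr::semi_join(small, by = c("group_label", "localization_class", "replicate_id")) |>
        dplyr::count(.data$group_label, name = "n_excluded_small_replicate"),
      by = "group_label"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_excluded"),
                                \(x) dplyr::coalesce(x, 0L))) |>
    dplyr::mutate(n_included = .data$n_seen - .data$n_excluded_undetermined -
                    .data$n_excluded_multi - .data$n_excluded_small_replicate)

  structure(
    list(replicate_means = replicate_means, group_means = group_means,
         exclusions = exclusions, min_ais_per_device = min_ais_per_device),
    class = "dimension_summary"
  )
}
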