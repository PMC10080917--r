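#' @export
generics::tidy

#' @export
generics::glance

#' Tidiers for aismorph result objects
#'
#' broom-style `tidy()` and `glance()` methods: `tidy()` returns the
#' per-element detail table, `glance()` a one-row (or one-row-per-group)
#' summary.
#'
#' @param x A `grubbs_test`, `chisq_homogeneity`, `dimension_summary` or
#'   `ais_experiment_report` object.
#' @param ... Unused.
#' @return A tibble.
#' @name aismorph-tidiers
NULL

#' @rdname aismorph-tidiers
#' @export
tidy.grubbs_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, critical = x$critical, alpha = x$alpha,
    n = x$n, flagged = x$flagged,
    outlier_index = x$outlier_index, outlier_value = x$outlier_value
  )
}

#' @rdname aismorph-tidiers
#' @export
glance.grubbs_test <- function(x, ...) tidy(x)

#' @export
print.grubbs_test <- function(x, ...) {
  cat(sprintf("Grubbs single-outlier test (alpha = %g, n = %d)\n", x$alpha, x$n))
  cat(sprintf("  G = %.4f, critical = %.4f\n", x$statistic, x$critical))
  if (x$flagged) {
    cat(sprintf("  flagged: value %g (index %d)\n", x$outlier_value, x$outlier_index))
  } else {
    cat("  no outlier flagged\n")
  }
  invisible(x)
}

#' @rdname aismorph-tidiers
#' @export
tidy.chisq_homogeneity <- function(x, ...) {
  obs <- as.data.frame(as.table(x$observed))
  names(obs) <- c("group", "class", "observed")
  exp <- as.data.frame(as.table(x$expected))
  obs$expected <- exp$Freq
  as_tibble(obs)
}

#' @rdname aismorph-tidiers
#' @export
glance.chisq_homogeneity <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         n_dropped_classes = length(x$dropped_columns))
}

#' @export
print.chisq_homogeneity <- function(x, ...) {
  cat(sprintf("Chi-square homogeneity: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (length(x$dropped_columns)) {
    cat("  dropped empty classes:", paste(x$dropped_columns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname aismorph-tidiers
#' @export
tidy.dimension_summary <- function(x, ...) x$replicate_means

#' @rdname aismorph-tidiers
#' @export
glance.dimension_summary <- function(x, ...) x$group_means

#' @export
print.dimension_summary <- function(x, ...) {
  cat("AIS dimension summary (replicate-level means)\n")
  print(x$group_means)
  cat("Exclusions:\n")
  print(x$exclusions)
  invisible(x)
}

#' @rdname aismorph-tidiers
#' @export
tidy.ais_experiment_report <- function(x, ...) x$measurements

#' @rdname aismorph-tidiers
#' @export
glance.ais_experiment_report <- function(x, ...) x$shift_recovery

#' @export
print.ais_experiment_report <- function(x, ...) {
  n_cells <- dplyr::n_distinct(x$truth$cell_id)
  cat(sprintf("Synthetic axonopathy experiment: %d cells x 2 arms\n", n_cells))
  cat("\nLocalization proportions:\n")
  print(x$localization$proportions |>
          dplyr::select("group_label", dplyr::starts_with("pct_")))
  cat("\nShift recovery (vehicle - axonopathy, um):\n")
  print(x$shift_recovery |>
          dplyr::select("localization_class", "recovered_shift_um",
                        "configured_shift_um", "length_change_um"))
  cat("\nExclusions:\n")
  print(x$dimensions$exclusions)
  invisible(x)
}
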