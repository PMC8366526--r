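#' Pooled standard deviations for paired standardization
#'
#' Two pooling rules standardize the living-shoreline minus natural-marsh
#' difference. The local (within-pair) rule pools the within-site replicate
#' SDs of the two members of a pair: sqrt((sd_ls^2 + sd_nm^2) / 2). The
#' regional (among-pair) rule pools the SD of living-shoreline site means
#' across pairs with the SD of natural-marsh site means across pairs, by
#' the same root-mean-square formula, yielding one shared value per metric.
#'
#' @param sd_ls,sd_nm Within-site replicate SDs of the living shoreline and
#'   natural marsh of one pair (both >= 0, not both 0).
#' @return The pooled SD.
#' @examples
#' pooled_sd_local(3, 4)  # sqrt(12.5)
#' @export
pooled_sd_local <- function(sd_ls, sd_nm) {
  if (any(!is.finite(c(sd_ls, sd_nm))) || sd_ls < 0 || sd_nm < 0) {
    abort("Within-site SDs must be finite and >= 0.")
  }
  if (sd_ls == 0 && sd_nm == 0) {
    abort("Degenerate SD: both within-site SDs are zero, Z undefined.")
  }
  sqrt((sd_ls^2 + sd_nm^2) / 2)
}

#' @rdname pooled_sd_local
#' @param ls_means,nm_means Site-level means, one per pair (>= 2 pairs).
#' @examples
#' pooled_sd_regional(c(1, 2, 3), c(2, 4, 6))  # sqrt(2.5)
#' @export
pooled_sd_regional <- function(ls_means, nm_means) {
  if (length(ls_means) < 2 || length(nm_means) < 2) {
    abort("Regional SD needs site means from at least 2 pairs.")
  }
  s <- sqrt((var(ls_means) + var(nm_means)) / 2)
  if (!is.finite(s) || s == 0) {
    abort("Degenerate SD: no among-pair variation, Z undefined.")
  }
  s
}

#' Standardized paired difference (Z-score)
#'
#' The natural-marsh site value is subtracted from the living-shoreline
#' value and divided by a pooled SD; positive scores mean the living
#' shoreline shows the higher level of function.
#'
#' @param ls_mean,nm_mean Site-level metric values.
#' @param pooled_sd Pooled SD (> 0), local or regional.
#' @return The dimensionless Z-score.
#' @examples
#' z_score(7, 5, 2)  # +1
#' @export
z_score <- function(ls_mean, nm_mean, pooled_sd) {
  if (any(pooled_sd <= 0) || any(!is.finite(pooled_sd))) {
    abort("`pooled_sd` must be > 0.")
  }
  (ls_mean - nm_mean) / pooled_sd
}

#' Build the pair-by-metric equivalence table
#'
#' Computes the Z-score of every pair-by-metric combination using the
#' pooled-SD mode registered for each metric (local within-pair SDs for
#' soils, invertebrates and plants; one regional among-pair SD for nekton,
#' heron and terrapin metrics), the per-pair net functional-equivalence
#' score (mean over the metrics included in the net score), the per-metric
#' mean over pairs, and the grand mean and SD. A metric is flagged
#' functionally equivalent when the absolute value of its mean Z-score is
#' below 1. Pairs with a degenerate (zero) pooled SD for a local metric are
#' excluded from that metric with a warning rather than returning infinite
#' scores.
#'
#' @param summaries Site-by-metric summary tibble from [summarize_sites()]
#'   (columns `pair`, `site_type`, `metric`, `mean`, `sd`, `n`).
#' @param metric_defs Metric registry; defaults to [metric_definitions()].
#' @return An object of class `equivalence_table`: a list with
#'   `z` (tibble `pair`, `metric`, `z`, `sd_mode`, `pooled_sd`,
#'   `in_net_score`), `net_scores` (tibble `pair`, `net_score`, plus the
#'   pair ages when the summaries came from a simulated design),
#'   `metric_means` (tibble `metric`, `mean_z`, `equivalent`),
#'   `grand_mean`, `grand_sd` (over all pair-by-metric scores) and
#'   `grand_sd_metrics` (over metric means).
#' @examples
#' obs <- simulate_study(study_design(seed = 1), effect_spec())
#' eq <- equivalence_table(summarize_sites(obs))
#' eq$metric_means
#' @export
equivalence_table <- function(summaries, metric_defs = metric_definitions()) {
  req <- c("pair", "site_type", "metric", "mean", "sd", "n")
  missing_cols <- setdiff(req, names(summaries))
  if (length(missing_cols)) {
    abort(sprintf("Summaries lack columns: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(unique(summaries$metric), metric_defs$metric)
  if (length(unknown)) {
    abort(sprintf("Metrics without definitions: %s.",
                  paste(unknown, collapse = ", ")))
  }

  wide <- summaries |>
    dplyr::select("pair", "site_type", "metric", "mean", "sd") |>
    tidyr::pivot_wider(names_from = "site_type",
                       values_from = c("mean", "sd"))
  incomplete <- wide$metric[!complete.cases(wide[, c("mean_LS", "mean_NM")])]
  if (length(incomplete)) {
    abort(sprintf(
      "Both members of each pair are required; gaps in: %s.",
      paste(unique(incomplete), collapse = ", ")))
  }

  defs <- metric_defs[match(wide$metric, metric_defs$metric), ]
  wide$sd_mode <- defs$sd_mode
  wide$in_net_score <- defs$in_net_score

  z_tbl <- wide |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_modify(function(df, key) {
      if (df$sd_mode[1] == "regional") {
        ps <- pooled_sd_regional(df$mean_LS, df$mean_NM)
        df$pooled_sd <- ps
        df$z <- z_score(df$mean_LS, df$mean_NM, ps)
      } else {
        ps <- purrr::map2_dbl(df$sd_LS, df$sd_NM, function(a, b) {
          if (is.na(a) || is.na(b)) return(NA_real_)
          if (a == 0 && b == 0) return(NA_real_)
          pooled_sd_local(a, b)
        })
        bad <- is.na(ps)
        if (any(bad)) {
          warn(sprintf(
            "Metric '%s': degenerate or missing within-site SD for pair(s) %s; excluded.",
            key$metric, paste(df$pair[bad], collapse = ", ")))
        }
        df$pooled_sd <- ps
        df$z <- ifelse(bad, NA_real_,
                       (df$mean_LS - df$mean_NM) / ps)
      }
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select("pair", "metric", "z", "sd_mode", "pooled_sd",
                  "in_net_score") |>
    dplyr::arrange(.data$pair, .data$metric)

  net <- z_tbl |>
    dplyr::filter(.data$in_net_score) |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(net_score = mean(.data$z, na.rm = TRUE),
                     .groups = "drop")

  metric_means <- z_tbl |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean_z = mean(.data$z, na.rm = TRUE),
                     in_net_score = .data$in_net_score[1],
                     .groups = "drop") |>
    dplyr::mutate(equivalent = abs(.data$mean_z) < 1)

  included <- z_tbl$z[z_tbl$in_net_score]
  metric_included <- metric_means$mean_z[metric_means$in_net_score]
  structure(
    list(z = z_tbl,
         net_scores = net,
         metric_means = metric_means,
         grand_mean = mean(included, na.rm = TRUE),
         grand_sd = sd(included[!is.na(included)]),
         grand_sd_metrics = sd(metric_included)),
    class = "equivalence_table")
}

#' @export
print.equivalence_table <- function(x, ...) {
  cat(sprintf(
    "<equivalence_table> %d pairs x %d metrics (net score over %d)\n",
    dplyr::n_distinct(x$z$pair), dplyr::n_distinct(x$z$metric),
    sum(x$metric_means$in_net_score)))
  cat(sprintf("grand mean Z = %.2f +/- %.2f (SD over pair x metric scores)\n",
              x$grand_mean, x$grand_sd))
  n_eq <- sum(x$metric_means$equivalent[x$metric_means$in_net_score])
  cat(sprintf("%d / %d net-score metrics equivalent (|mean Z| < 1)\n",
              n_eq, sum(x$metric_means$in_net_score)))
  invisible(x)
}

#' @describeIn equivalence_table Tidy pair-by-metric Z-scores.
#' @param x An `equivalence_table`.
#' @param ... Unused.
#' @export
tidy.equivalence_table <- function(x, ...) x$z

#' @describeIn equivalence_table One-row summary (grand mean/SD, counts).
#' @export
glance.equivalence_table <- function(x, ...) {
  tibble::tibble(
    n_pairs = dplyr::n_distinct(x$z$pair),
    n_metrics = dplyr::n_distinct(x$z$metric),
    grand_mean = x$grand_mean,
    grand_sd = x$grand_sd,
    n_equivalent = sum(x$metric_means$equivalent[x$metric_means$in_net_score]))
}

#' @describeIn equivalence_table Dot plot of pair-level Z-scores per metric
#'   with the equivalence band.
#' @param object An `equivalence_table`.
#' @export
autoplot.equivalence_table <- function(object, ...) {
  df <- dplyr::filter(object$z, !is.na(.data$z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$metric)) +
    ggplot2::annotate("rect", xmin = -1, xmax = 1, ymin = -Inf, ymax = Inf,
                      alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, colour = "firebrick", geom = "point",
                          shape = 18, size = 3) +
    ggplot2::labs(x = "Z-score (LS - NM, pooled-SD units)", y = NULL) +
    ggplot2::theme_minimal()
}
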