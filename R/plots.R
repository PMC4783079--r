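#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the per-round AUC distribution of a cross-validation run
#'
#' @param object a [cross_validate()] result.
#' @param ... ignored.
#' @return A ggplot.
#' @export
#' @method autoplot dr_cv
autoplot.dr_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$mean_auc, colour = "red") +
    ggplot2::labs(
      title = paste0("Classifier ", object$classifier, ": mean AUC ",
                     sprintf("%.3f", object$mean_auc)),
      x = paste0("per-round AUC (", object$rounds, " rounds of ",
                 object$folds, "-fold CV)"),
      y = "rounds"
    ) +
    ggplot2::theme_minimal()
}

#' Compare mean cross-validated AUC across classifiers
#'
#' @param cv_tbl result of [cross_validate_all()].
#' @return A ggplot bar chart in classifier order S, T, E, ST, SE, TE,
#'   STE.
#' @export
plot_cv_summary <- function(cv_tbl) {
  df <- dplyr::mutate(cv_tbl,
                      classifier = factor(.data$classifier,
                                          levels = dr_classifier_names()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$classifier,
                                   y = .data$mean_auc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_auc - .data$sd_auc,
                   ymax = .data$mean_auc + .data$sd_auc),
      width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "classifier", y = "mean CV AUC") +
    ggplot2::theme_minimal()
}

#' Plot per-assay AUC distributions by classifier and hit category
#'
#' @param hts_results per-classifier assay evaluation table (e.g. the
#'   `hts` element of [run_pipeline()]).
#' @return A ggplot boxplot.
#' @export
plot_hts_auc <- function(hts_results) {
  long <- hts_results |>
    tidyr::pivot_longer(c("auc_anticancer", "auc_novel"),
                        names_to = "category", values_to = "auc",
                        names_prefix = "auc_") |>
    dplyr::filter(!is.na(.data$auc)) |>
    dplyr::mutate(classifier = factor(.data$classifier,
                                      levels = dr_classifier_names()))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$classifier, y = .data$auc,
                                     fill = .data$category)) +
    ggplot2::geom_boxplot(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "classifier", y = "per-assay AUC") +
    ggplot2::theme_minimal()
}

#' Heat map of an enrichment profile
#'
#' Tiles are `-log10` representative p-values, faceted by direction;
#' shows only pathways significant in at least one profiled drug by
#' default.
#'
#' @param object an [enrich_drugs()] tibble.
#' @param significant_only restrict to pathways with a significant row.
#'   Default `TRUE`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
#' @method autoplot enrichment_profile
autoplot.enrichment_profile <- function(object, significant_only = TRUE,
                                        ...) {
  df <- tibble::as_tibble(object)
  if (significant_only) {
    keep <- unique(df$pathway_id[df$significant])
    df <- df[df$pathway_id %in% keep, ]
  }
  df <- dplyr::mutate(df, neglogp = -log10(.data$p_rep))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$drug_id, y = .data$pathway_id,
                                   fill = .data$neglogp)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~direction) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = expression(-log[10] ~ p)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a mode-of-action clustering as an annotated distance heat map
#'
#' @param object a [cluster_profiles()] result.
#' @param ... ignored.
#' @return A ggplot of the cosine distance matrix, drugs ordered by the
#'   dendrogram.
#' @export
#' @method autoplot moa_clustering
autoplot.moa_clustering <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  df <- tibble::as_tibble(object$distances, rownames = "a") |>
    tidyr::pivot_longer(-"a", names_to = "b", values_to = "distance") |>
    dplyr::mutate(a = factor(.data$a, levels = ord),
                  b = factor(.data$b, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "firebrick", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cosine\ndistance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
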