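#' Partition an HTS assay's hits into known / anti-cancer / novel
#'
#' Known drugs are removed from the hit list first (the goal is novel
#' repositioning, not rediscovery). Remaining hits are *anti-cancer* if
#' they belong to the CD set or have at least `min_analogs` structural
#' analogs in the CD set at fingerprint Tanimoto strictly above
#' `analog_threshold` — i.e. hits that structure-based methods would find
#' anyway; the rest are *novel* hits, the hard and interesting cases.
#' Tested non-hits form the negative pool. When a compound carries several
#' S signatures the analog comparison uses the maximum Tanimoto over
#' signature pairs (the permissive reading of "has an analog"); hits
#' without any S signature are classified by CD membership alone, logged.
#'
#' @param assay either an assay id present in `catalog$assays` or a tibble
#'   with `compound_id` and `hit` columns.
#' @param catalog a [dr_catalog()].
#' @param analog_threshold Tanimoto cut for a CD analog, strict. Default
#'   0.7.
#' @param min_analogs analogs needed to call a hit anti-cancer. Default 2.
#' @param scope evaluation universe; default the core set.
#' @return A list of class `hit_partition`: `assay_id`, `excluded_known`,
#'   `anticancer_hits`, `novel_hits`, `nonhits` (disjoint character
#'   vectors partitioning tested-in-scope compounds).
#' @export
partition_hits <- function(assay, catalog, analog_threshold = 0.7,
                           min_analogs = 2, scope = NULL) {
  if (is.character(assay) && length(assay) == 1) {
    assay_id <- assay
    assay <- dplyr::filter(catalog$assays, .data$assay_id == !!assay)
    if (nrow(assay) == 0) abort(paste0("unknown assay: ", assay_id))
  } else {
    assay_id <- assay$assay_id[1] %||% "assay"
  }
  scope <- scope %||% core_set(catalog)
  tested <- intersect(assay$compound_id, scope)
  hits <- intersect(assay$compound_id[assay$hit], tested)
  if (length(hits) == 0) {
    warn(paste0("assay ", assay_id, ": no in-scope hits"))
  }
  kd <- catalog$disease$kd_ids
  cd <- catalog$disease$cd_ids
  excluded_known <- intersect(hits, kd)
  rest <- setdiff(hits, kd)

  by_cd <- intersect(rest, cd)
  need_analog <- setdiff(rest, cd)
  by_analog <- character()
  if (length(need_analog) > 0) {
    s <- catalog$signatures[catalog$signatures$sig_type == "S", ]
    cd_s <- s[s$owner_id %in% cd, ]
    hit_s <- s[s$owner_id %in% need_analog, ]
    no_s <- setdiff(need_analog, hit_s$owner_id)
    if (length(no_s) > 0) {
      inform(paste0("assay ", assay_id, ": ", length(no_s),
                    " hit(s) without S signature classified by CD ",
                    "membership alone"))
    }
    if (nrow(hit_s) > 0 && nrow(cd_s) > 0) {
      sim <- tanimoto_cross(hit_s$features, cd_s$features)
      by_analog <- vapply(unique(hit_s$owner_id), function(id) {
        block <- sim[hit_s$owner_id == id, , drop = FALSE]
        # max over this hit's fingerprints, per CD compound
        per_cd <- tapply(apply(block, 2, max), cd_s$owner_id, max)
        sum(per_cd > analog_threshold) >= min_analogs
      }, logical(1))
      by_analog <- names(by_analog)[by_analog]
    }
  }
  anticancer <- sort(union(by_cd, by_analog))
  novel <- sort(setdiff(rest, anticancer))
  structure(
    list(assay_id = assay_id,
         excluded_known = sort(excluded_known),
         anticancer_hits = anticancer,
         novel_hits = novel,
         nonhits = sort(setdiff(tested, hits))),
    class = "hit_partition"
  )
}

#' @export
print.hit_partition <- function(x, ...) {
  cat("<hit_partition> ", x$assay_id, ": ",
      length(x$excluded_known), " known (excluded), ",
      length(x$anticancer_hits), " anti-cancer, ",
      length(x$novel_hits), " novel, ",
      length(x$nonhits), " non-hits\n", sep = "")
  invisible(x)
}

#' Evaluate DR scores against a partitioned assay
#'
#' Two AUCs per assay: anti-cancer hits vs non-hits and novel hits vs
#' non-hits. Known-drug hits and the opposite hit category never enter the
#' negatives. An empty positive category yields `NA` for that AUC (never
#' 0).
#'
#' @param scores tibble with `compound_id`, `dr_score`.
#' @param partition a [partition_hits()] result.
#' @return A one-row tibble: `assay_id`, counts, `auc_anticancer`,
#'   `auc_novel`.
#' @export
evaluate_assay <- function(scores, partition) {
  sc <- setNames(scores$dr_score, scores$compound_id)
  auc_for <- function(pos) {
    neg <- setdiff(partition$nonhits,
                   c(partition$excluded_known, partition$anticancer_hits,
                     partition$novel_hits))
    pos <- intersect(pos, names(sc))
    neg <- intersect(neg, names(sc))
    if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
    roc_auc(sc, pos, neg)
  }
  tibble::tibble(
    assay_id = partition$assay_id,
    n_tested = length(partition$nonhits) + length(partition$excluded_known) +
      length(partition$anticancer_hits) + length(partition$novel_hits),
    n_excluded_known = length(partition$excluded_known),
    n_anticancer = length(partition$anticancer_hits),
    n_novel = length(partition$novel_hits),
    auc_anticancer = auc_for(partition$anticancer_hits),
    auc_novel = auc_for(partition$novel_hits)
  )
}

#' Evaluate DR scores against every assay in the catalog
#'
#' @param scores tibble with `compound_id`, `dr_score`.
#' @param catalog a [dr_catalog()] with assays.
#' @param all_compounds evaluate over all assayed compounds instead of the
#'   core set. Default `FALSE`.
#' @inheritParams partition_hits
#' @return A tibble with one [evaluate_assay()] row per assay.
#' @export
evaluate_hts <- function(scores, catalog, analog_threshold = 0.7,
                         min_analogs = 2, all_compounds = FALSE) {
  if (is.null(catalog$assays)) abort("catalog has no HTS assays")
  scope <- if (all_compounds) catalog$compounds$compound_id else
    core_set(catalog)
  ids <- unique(catalog$assays$assay_id)
  dplyr::bind_rows(lapply(ids, function(a) {
    part <- partition_hits(a, catalog, analog_threshold = analog_threshold,
                           min_analogs = min_analogs, scope = scope)
    evaluate_assay(scores, part)
  }))
}

#' Summarise per-assay AUCs
#'
#' Median AUC per hit category over assays; missing AUCs are omitted from
#' the medians (a category can be empty in a given assay), and a category
#' missing in every assay is dropped with a warning.
#'
#' @param results tibble of [evaluate_assay()] rows (possibly several
#'   classifiers; pass a `classifier` column to keep them apart).
#' @return A long tibble: optional `classifier`, `category`, `median_auc`,
#'   `n_assays`.
#' @export
summarize_assays <- function(results) {
  if (nrow(results) == 0) abort("no assay results to summarise")
  grouping <- intersect("classifier", names(results))
  long <- results |>
    tidyr::pivot_longer(c("auc_anticancer", "auc_novel"),
                        names_to = "category", values_to = "auc",
                        names_prefix = "auc_") |>
    dplyr::filter(!is.na(.data$auc))
  missing_cat <- setdiff(c("anticancer", "novel"), unique(long$category))
  if (length(missing_cat) > 0) {
    warn(paste0("no assay produced an AUC for category: ",
                paste(missing_cat, collapse = ", ")))
  }
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "category")))) |>
    dplyr::summarise(median_auc = median(.data$auc),
                     n_assays = dplyr::n(), .groups = "drop")
}
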