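#' Run the full repositioning pipeline
#'
#' Wires the stages end to end over a synthetic world (or a catalog
#' loaded from a config): association features (with leave-self-out
#' features for cross-validation), cross-validated AUC for all seven
#' classifiers, DR scores and percentile ranks from the chosen scoring
#' classifier, candidate filtering, HTS benchmark evaluation of every
#' classifier, pathway enrichment of the candidate/known-drug panel and
#' mode-of-action clustering. Every stage writes its table before the
#' next starts, a stage failure aborts naming the stage and preserves
#' prior outputs, and a `manifest.json` records parameters, seed and
#' output checksums. Identical inputs and seed reproduce identical
#' outputs.
#'
#' @param out_dir output directory.
#' @param world optional [generate_world()] result; by default one is
#'   generated from `params`.
#' @param params [world_params()] used when `world` is `NULL`;
#'   `params$seed` is replaced by `seed`.
#' @param catalog optionally, a [dr_catalog()] to analyse instead of a
#'   synthetic world (skips truth-dependent reporting).
#' @param seed integer seed for world generation and cross-validation.
#' @param score_classifier classifier used for final scores and ranking;
#'   default `"E"`.
#' @param rounds,folds cross-validation scheme (100 x 3-fold).
#' @param threshold candidate percentile cut (strict), default 0.9.
#' @param q_cutoff enrichment significance cut, default 0.1.
#' @param n_enrich_drugs cap on the number of drugs profiled for
#'   enrichment (candidates first, then known drugs), default 30.
#' @return Invisibly, a list with the main tables (`cv`, `scores`,
#'   `candidates`, `hts`, `hts_summary`, `enrichment`, `clustering`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(out_dir, world = NULL, params = world_params(),
                         catalog = NULL, seed = 1,
                         score_classifier = "E", rounds = 100, folds = 3,
                         threshold = 0.9, q_cutoff = 0.1,
                         n_enrich_drugs = 30) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  outputs <- character()
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    readr::write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }

  if (is.null(catalog)) {
    world <- world %||% stage("simulate", {
      params$seed <- seed
      generate_world(params)
    })
    catalog <- world$catalog
    stage("simulate", write_world(world, file.path(out_dir, "world")))
  }

  feats <- stage("build-features", {
    f <- build_association_features(catalog)
    emit(f, "features.tsv")
    f
  })
  feats_loo <- stage("build-features",
                     build_association_features(catalog, loo_kd = TRUE))
  labels <- stage("benchmark", make_benchmark(catalog))

  cv <- stage("cv-eval", {
    res <- cross_validate_all(feats_loo, labels, rounds = rounds,
                              folds = folds, seed = seed)
    emit(dplyr::select(res, -"cv"), "cv_auc.tsv")
    jsonlite::write_json(
      lapply(stats::setNames(res$cv, res$classifier),
             function(x) x$round_aucs),
      file.path(out_dir, "cv_round_aucs.json"), digits = NA
    )
    res
  })

  scores <- stage("score", {
    model <- fit_dr_model(feats, labels, classifier = score_classifier)
    sc <- percentile_rank(dr_score(model, feats))
    emit(sc, "scores.tsv")
    sc
  })

  candidates <- stage("filter", {
    cand <- filter_candidates(scores, catalog, threshold = threshold)
    emit(cand, "candidates.tsv")
    cand
  })

  hts <- hts_summary <- NULL
  if (!is.null(catalog$assays)) {
    hts <- stage("hts-eval", {
      per_cl <- dplyr::bind_rows(lapply(dr_classifier_names(), function(cl) {
        m <- fit_dr_model(feats_loo, labels, classifier = cl)
        sc <- dr_score(m, feats_loo)
        dplyr::mutate(evaluate_hts(sc, catalog), classifier = cl,
                      .before = 1)
      }))
      emit(per_cl, "hts_eval.tsv")
      per_cl
    })
    hts_summary <- stage("hts-eval", {
      s <- summarize_assays(hts)
      emit(s, "hts_medians.tsv")
      s
    })
  }

  enrichment <- clustering <- NULL
  if (!is.null(catalog$pathways)) {
    enrich_ids <- stage("enrich", {
      ids <- unique(c(candidates$compound_id, catalog$disease$kd_ids))
      with_e <- unique(catalog$signatures$owner_id[
        catalog$signatures$sig_type == "E"])
      head(intersect(ids, with_e), n_enrich_drugs)
    })
    enrichment <- stage("enrich", {
      prof <- enrich_drugs(catalog, enrich_ids, q_cutoff = q_cutoff)
      emit(prof, "enrichment.tsv")
      prof
    })
    clustering <- stage("cluster", {
      cl <- tryCatch(cluster_profiles(enrichment),
                     error = function(e) NULL)
      if (is.null(cl)) {
        warn("clustering skipped: no significant pathway rows")
      } else {
        emit(tibble::tibble(drug_id = names(cl$clusters),
                            cluster = unname(cl$clusters)),
             "clusters.tsv")
        dm <- tibble::as_tibble(cl$distances, rownames = "drug_id")
        emit(dm, "distances.tsv")
        if (requireNamespace("ape", quietly = TRUE)) {
          write_dendrogram_newick(cl, file.path(out_dir, "dendrogram.nwk"))
        }
      }
      cl
    })
  } else {
    warn("no pathway collection; enrichment stage skipped")
  }

  manifest <- list(
    command = "run_pipeline",
    seed = seed,
    parameters = list(score_classifier = score_classifier,
                      rounds = rounds, folds = folds,
                      threshold = threshold, q_cutoff = q_cutoff,
                      world = if (!is.null(world)) unclass(world$params)),
    outputs = as.list(tools::md5sum(sort(outputs))),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cv = cv, scores = scores, candidates = candidates,
                 hts = hts, hts_summary = hts_summary,
                 enrichment = enrichment, clustering = clustering,
                 out_dir = out_dir))
}
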