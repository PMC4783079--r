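#' Tanimoto similarity of two finite sets
#'
#' `|a intersect b| / |a union b|` — the Jaccard/Tanimoto coefficient,
#' which is the natural similarity for signatures viewed as binary
#' presence/absence vectors (fingerprint on-bits, gene sets).
#'
#' @param a,b character (or coercible) vectors, interpreted as sets.
#' @return A number in `[0, 1]`; 1 iff the sets are equal, 0 iff disjoint.
#' @export
#' @examples
#' tanimoto(c("g1", "g2", "g3"), c("g2", "g3", "g4")) # 0.5
tanimoto <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0 && length(b) == 0) {
    abort("tanimoto of two empty sets is undefined")
  }
  n_int <- sum(a %in% b)
  n_int / (length(a) + length(b) - n_int)
}

# All pairwise Tanimoto coefficients between two lists of sets, via a
# sparse incidence crossproduct (|intersections| in one multiply).
tanimoto_cross <- function(sets_a, sets_b) {
  toks <- unique(c(unlist(sets_a, use.names = FALSE),
                   unlist(sets_b, use.names = FALSE)))
  enc <- function(sets) {
    idx <- lapply(sets, function(s) match(unique(s), toks))
    Matrix::sparseMatrix(
      i = unlist(idx), j = rep(seq_along(sets), lengths(idx)),
      x = 1, dims = c(length(toks), length(sets))
    )
  }
  ma <- enc(sets_a)
  mb <- enc(sets_b)
  inter <- as.matrix(Matrix::crossprod(ma, mb))
  sizes_a <- Matrix::colSums(ma)
  sizes_b <- Matrix::colSums(mb)
  inter / (outer(sizes_a, sizes_b, `+`) - inter)
}

#' Mean pairwise Tanimoto similarity between two signature pools
#'
#' Compounds and diseases can own several signatures (multiple cell
#' contexts, multiple datasets); the association between the two sides is
#' the arithmetic mean of the Tanimoto coefficient over the full Cartesian
#' product of (compound signature, reference signature) pairs.
#'
#' @param compound_sets,reference_sets lists of feature sets (character
#'   vectors).
#' @return Mean Tanimoto in `[0, 1]`, or `NA_real_` if either list is
#'   empty (missing-feature marker, resolved by the feature builder).
#' @export
mean_pairwise_similarity <- function(compound_sets, reference_sets) {
  if (length(compound_sets) == 0 || length(reference_sets) == 0) {
    return(NA_real_)
  }
  mean(tanimoto_cross(compound_sets, reference_sets))
}

#' The fixed association-feature vocabulary
#'
#' Seven compound-disease similarity features: structure vs known-drug
#' structures (`S_S`); compound targets vs known-drug targets (`T_T`),
#' known-drug expression (`T_Ekd`) and disease expression (`T_Edis`); and
#' compound expression vs the same three reference pools (`E_T`, `E_Ekd`,
#' `E_Edis`).
#'
#' @return Character vector of the seven feature names.
#' @export
dr_feature_names <- function() {
  c("S_S", "T_T", "T_Ekd", "T_Edis", "E_T", "E_Ekd", "E_Edis")
}

# Disease-side pools, as flat lists of combined feature sets, with the
# owning compound id attached so leave-self-out pools can be formed.
disease_pools <- function(catalog, directional = FALSE) {
  kd <- catalog$disease$kd_ids
  sigs <- catalog$signatures
  kd_sigs <- combine_signatures(sigs[sigs$owner_id %in% kd, ],
                                directional = directional)
  pool <- function(type) {
    rows <- kd_sigs[kd_sigs$sig_type == type, ]
    list(sets = rows$features, owner = rows$owner_id,
         direction = rows$direction)
  }
  dis <- combine_signatures(catalog$disease$signatures,
                            directional = directional)
  list(
    S_kd = pool("S"), T_kd = pool("T"), E_kd = pool("E"),
    E_dis = list(sets = dis$features, owner = dis$owner_id,
                 direction = dis$direction)
  )
}

# Mean over the Cartesian product, optionally leaving one compound's own
# signatures out of the reference pool (exact: recomputed from the full
# pairwise matrix, since the pool mean is a flat mean over pairs).
pool_feature <- function(cpd_sets_by_id, pool, loo_ids = character(),
                         directional = FALSE) {
  ids <- names(cpd_sets_by_id)
  out <- setNames(rep(NA_real_, length(ids)), ids)
  keep <- lengths(cpd_sets_by_id) > 0
  if (!any(keep) || length(pool$sets) == 0) return(out)

  compute_block <- function(cpd_rows, pool_rows) {
    # cpd_rows / pool_rows: tibbles with id/owner and sets
    sim <- tanimoto_cross(cpd_rows$sets, pool_rows$sets)
    vapply(ids, function(id) {
      ci <- which(cpd_rows$id == id)
      if (length(ci) == 0) return(NA_real_)
      pj <- if (id %in% loo_ids) which(pool_rows$owner != id) else
        seq_along(pool_rows$owner)
      if (length(pj) == 0) return(NA_real_)
      mean(sim[ci, pj, drop = FALSE])
    }, numeric(1))
  }

  cpd_ids_flat <- rep(ids[keep], lengths(cpd_sets_by_id[keep]))
  cpd_dirs <- unlist(lapply(cpd_sets_by_id[keep], function(x) {
    attr(x, "direction") %||% rep("combined", length(x))
  }))
  cpd_rows <- list(id = cpd_ids_flat,
                   sets = unlist(cpd_sets_by_id[keep], recursive = FALSE),
                   direction = cpd_dirs)

  if (!directional || all(pool$direction %in% c("na", "combined"))) {
    vals <- compute_block(cpd_rows, list(owner = pool$owner,
                                         sets = pool$sets))
    return(vals)
  }
  # Direction-matched: average the up<->up and down<->down means.
  per_dir <- lapply(c("up", "down"), function(d) {
    ci <- cpd_rows$direction == d
    pj <- pool$direction == d
    if (!any(ci) || !any(pj)) return(setNames(rep(NA_real_, length(ids)), ids))
    compute_block(list(id = cpd_rows$id[ci],
                       sets = cpd_rows$sets[ci]),
                  list(owner = pool$owner[pj], sets = pool$sets[pj]))
  })
  rowMeans(cbind(per_dir[[1]], per_dir[[2]]))
}

#' Build the compound-disease association feature table
#'
#' For every compound, up to seven similarity features against the
#' disease-side reference pools: the pooled signatures of the disease's
#' known drugs (S, T and E pools) and the disease expression signatures.
#' Each feature is the mean Tanimoto coefficient over all (compound
#' signature, pool signature) pairs. A feature is `NA` exactly when the
#' compound lacks the needed signature type or the disease side lacks the
#' needed pool; missingness is preserved (not coerced to zero) because the
#' evaluation universe is the core set where all types exist.
#'
#' @param catalog a [dr_catalog()].
#' @param features which features to compute; default all seven.
#' @param directional compute direction-matched (up-up / down-down) E
#'   similarities instead of combined presence/absence sets. Default
#'   `FALSE`: a signature is a single binary vector of feature presence.
#' @param loo_kd leave-self-out pools for known drugs: each KD compound's
#'   own signatures are removed from the disease-side pools when scoring
#'   that compound. Used during cross-validation to prevent leakage;
#'   default `FALSE` (descriptive scores keep full pools).
#' @param compound_ids compounds to score; default all in the catalog.
#' @return A tibble: `compound_id`, `disease_id`, then one column per
#'   requested feature (values in `[0, 1]` or `NA`).
#' @export
build_association_features <- function(catalog,
                                       features = dr_feature_names(),
                                       directional = FALSE,
                                       loo_kd = FALSE,
                                       compound_ids = NULL) {
  bad <- setdiff(features, dr_feature_names())
  if (length(bad) > 0) {
    abort(paste0("unknown feature name(s): ", paste(bad, collapse = ", ")))
  }
  if (length(catalog$disease$kd_ids) == 0) {
    abort("disease has an empty KD set: no positives to define reference pools")
  }
  ids <- compound_ids %||% catalog$compounds$compound_id
  pools <- disease_pools(catalog, directional = directional)
  loo_ids <- if (loo_kd) catalog$disease$kd_ids else character()

  cpd <- combine_signatures(
    catalog$signatures[catalog$signatures$owner_id %in% ids, ],
    directional = directional
  )
  sets_of <- function(type) {
    rows <- cpd[cpd$sig_type == type, ]
    out <- lapply(setNames(ids, ids), function(id) {
      w <- rows$owner_id == id
      s <- rows$features[w]
      attr(s, "direction") <- rows$direction[w]
      s
    })
    out
  }
  side <- list(S = sets_of("S"), T = sets_of("T"), E = sets_of("E"))
  spec <- list(
    S_S = c("S", "S_kd"), T_T = c("T", "T_kd"), T_Ekd = c("T", "E_kd"),
    T_Edis = c("T", "E_dis"), E_T = c("E", "T_kd"), E_Ekd = c("E", "E_kd"),
    E_Edis = c("E", "E_dis")
  )
  out <- tibble::tibble(compound_id = ids,
                        disease_id = catalog$disease$disease_id)
  for (f in features) {
    cp_type <- spec[[f]][1]
    pool <- pools[[spec[[f]][2]]]
    dir_match <- directional && cp_type == "E" &&
      spec[[f]][2] %in% c("E_kd", "E_dis")
    out[[f]] <- unname(pool_feature(side[[cp_type]], pool,
                                    loo_ids = loo_ids,
                                    directional = dir_match))
  }
  out
}

#' Write an association feature table as TSV
#'
#' Missing features are encoded `NA`; comment header lines (`#`) carry the
#' disease id and a parameter echo for provenance.
#'
#' @param features feature tibble from [build_association_features()].
#' @param path output path.
#' @param params optional named list echoed into the header.
#' @return `path`, invisibly.
#' @export
write_association_features <- function(features, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# disease_id=", features$disease_id[1]), con)
  for (nm in names(params)) {
    writeLines(paste0("# ", nm, "=",
                      paste(unlist(params[[nm]]), collapse = ",")), con)
  }
  readr::write_tsv(dplyr::select(features, -"disease_id"), con)
  invisible(path)
}
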