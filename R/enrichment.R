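#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` with `k` the signature/pathway overlap, drawing
#' `n = |signature ∩ universe|` from `N = |universe|` containing
#' `K = |pathway ∩ universe|` successes. `k = 0` gives exactly 1.
#'
#' @param signature_genes,pathway_genes,universe character vectors
#'   (sets).
#' @return p in `(0, 1]`.
#' @export
hypergeom_p <- function(signature_genes, pathway_genes, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("empty enrichment universe")
  sig <- intersect(unique(signature_genes), universe)
  pw <- intersect(unique(pathway_genes), universe)
  if (length(sig) == 0) abort("signature has no genes in the universe")
  k <- length(intersect(sig, pw))
  if (k == 0) return(1)
  phyper(k - 1, length(pw), length(universe) - length(pw), length(sig),
         lower.tail = FALSE)
}

#' Harmonic mean of p-values
#'
#' `m / sum(1/p_i)` — the representative p-value summarising a drug's
#' per-cell-context enrichment p-values for one pathway. Dominated by the
#' smallest input, so a pathway enriched in a single context keeps a
#' strong representative value; always at most the arithmetic mean.
#'
#' @param p numeric vector with values in `(0, 1]`.
#' @return The harmonic mean, in `(0, 1]`.
#' @export
harmonic_mean_p <- function(p) {
  if (length(p) == 0) abort("harmonic mean of an empty p-value list")
  if (any(p <= 0) || anyNA(p)) abort("p-values must be in (0, 1]")
  length(p) / sum(1 / p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] (`method = "BH"`), kept as a
#' named operation so the adjustment family is explicit at call sites.
#'
#' @param p numeric vector in `(0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) abort("p-values must be in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Pathway enrichment profile of one drug
#'
#' For every (pathway, direction) pair: the hypergeometric enrichment
#' p-value of the drug's up- (or down-) regulated gene set is computed in
#' each cell context, the per-context p-values are aggregated by harmonic
#' mean into a representative p, and BH adjustment is applied within the
#' drug across all pathway-direction rows. `overlap` reports the largest
#' per-context overlap count.
#'
#' @param catalog a [dr_catalog()] with a pathway collection, or a
#'   signature tibble accompanied by `pathways`.
#' @param drug_id compound to profile; must have E signatures with both
#'   directions.
#' @param pathways optional [pathway_collection()] (defaults to
#'   `catalog$pathways`).
#' @param q_cutoff significance flag threshold on q. Default 0.1.
#' @return A tibble of class `enrichment_profile`: `drug_id`,
#'   `pathway_id`, `direction`, `p_rep`, `q`, `overlap`, `significant` —
#'   one row per retained pathway x direction.
#' @export
enrich_drug <- function(catalog, drug_id, pathways = NULL, q_cutoff = 0.1) {
  if (inherits(catalog, "dr_catalog")) {
    sigs <- catalog$signatures
    pathways <- pathways %||% catalog$pathways
  } else {
    sigs <- catalog
  }
  if (is.null(pathways)) abort("no pathway collection supplied")
  e <- sigs[sigs$owner_id == drug_id & sigs$sig_type == "E" &
              sigs$direction %in% c("up", "down"), ]
  if (nrow(e) == 0) abort(paste0("drug '", drug_id, "' has no E signatures"))
  universe <- pathways$universe
  pw <- pathways$pathways

  rows <- tidyr::expand_grid(pathway_id = names(pw),
                             direction = c("up", "down"))
  res <- purrr::pmap_dfr(rows, function(pathway_id, direction) {
    ctx <- e[e$direction == direction, ]
    if (nrow(ctx) == 0) {
      return(tibble::tibble(pathway_id = pathway_id, direction = direction,
                            p_rep = NA_real_, overlap = NA_integer_))
    }
    ps <- vapply(ctx$features, hypergeom_p, numeric(1),
                 pathway_genes = pw[[pathway_id]], universe = universe)
    ks <- vapply(ctx$features, function(g) {
      length(intersect(intersect(g, universe), pw[[pathway_id]]))
    }, integer(1))
    tibble::tibble(pathway_id = pathway_id, direction = direction,
                   p_rep = harmonic_mean_p(ps), overlap = max(ks))
  })
  res <- res |>
    dplyr::mutate(drug_id = drug_id,
                  q = bh_adjust(.data$p_rep),
                  significant = !is.na(.data$q) & .data$q < q_cutoff) |>
    dplyr::select("drug_id", "pathway_id", "direction", "p_rep", "q",
                  "overlap", "significant")
  class(res) <- c("enrichment_profile", class(res))
  res
}

#' Enrichment profiles for several drugs
#'
#' @inheritParams enrich_drug
#' @param drug_ids compounds to profile.
#' @return A long tibble of stacked [enrich_drug()] profiles.
#' @export
enrich_drugs <- function(catalog, drug_ids, pathways = NULL,
                         q_cutoff = 0.1) {
  out <- dplyr::bind_rows(lapply(drug_ids, function(d) {
    enrich_drug(catalog, d, pathways = pathways, q_cutoff = q_cutoff)
  }))
  class(out) <- c("enrichment_profile", class(out))
  out
}

#' Cosine distance between two nonnegative vectors
#'
#' `1 - u.v / (|u||v|)`; in `[0, 1]` for nonnegative vectors such as
#' `-log10 p` profiles.
#'
#' @param u,v numeric vectors of equal length, nonnegative, nonzero norm.
#' @return Cosine distance.
#' @export
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort("cosine distance undefined for a zero vector (unprofiled drug)")
  }
  1 - sum(u * v) / (nu * nv)
}

# -log10 p profile matrix (drugs x selected pathway-direction columns)
profile_matrix <- function(profiles, subset_keys) {
  profiles <- dplyr::mutate(profiles,
                            key = paste(.data$pathway_id, .data$direction,
                                        sep = "|"))
  wide <- profiles |>
    dplyr::filter(.data$key %in% subset_keys) |>
    dplyr::mutate(neglogp = -log10(.data$p_rep)) |>
    tidyr::pivot_wider(id_cols = "drug_id", names_from = "key",
                       values_from = "neglogp") |>
    dplyr::arrange(.data$drug_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  m[is.na(m)] <- 0
  rownames(m) <- wide$drug_id
  m[, sort(colnames(m)), drop = FALSE]
}

#' Cluster drugs by their pathway enrichment profiles
#'
#' Drug mode-of-action vectors are `-log10` representative p-values over a
#' pathway-direction subset (by default, rows significant at
#' `subset_q_cutoff` in at least one profile — the perturbed-pathway
#' panel). Pairwise cosine distances feed average-linkage agglomerative
#' clustering; flat clusters come from cutting the tree at `k` groups or
#' height `h`. Drugs are ordered lexicographically first, which makes the
#' dendrogram deterministic under ties.
#'
#' @param profiles long enrichment tibble ([enrich_drugs()]) covering at
#'   least two drugs.
#' @param pathway_subset optional character vector of
#'   `"<pathway>|<up|down>"` keys; default rows with
#'   `q < subset_q_cutoff` in any profile.
#' @param subset_q_cutoff default 0.05.
#' @param k number of flat clusters (default 2); ignored if `h` given.
#' @param h optional distance cut height.
#' @return A list of class `moa_clustering`: `hclust`, `clusters` (named
#'   integer vector), `distances` (symmetric matrix), `matrix` (the
#'   profile matrix), `pathway_subset`.
#' @export
cluster_profiles <- function(profiles, pathway_subset = NULL,
                             subset_q_cutoff = 0.05, k = 2, h = NULL) {
  if (length(unique(profiles$drug_id)) < 2) {
    abort("need at least two drug profiles to cluster")
  }
  if (is.null(pathway_subset)) {
    sig <- profiles[!is.na(profiles$q) & profiles$q < subset_q_cutoff, ]
    pathway_subset <- sort(unique(paste(sig$pathway_id, sig$direction,
                                        sep = "|")))
  }
  if (length(pathway_subset) == 0) {
    abort("pathway subset is empty; loosen subset_q_cutoff")
  }
  m <- profile_matrix(profiles, pathway_subset)
  zero <- rowSums(m^2) == 0
  if (any(zero)) {
    warn(paste0("dropping unprofiled drug(s) with all-zero vectors: ",
                paste(rownames(m)[zero], collapse = ", ")))
    m <- m[!zero, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("fewer than two profiled drugs after filtering")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- cosine_distance(m[i, ], m[j, ])
    }
  }
  hc <- hclust(as.dist(d), method = "average")
  cl <- if (is.null(h)) cutree(hc, k = k) else cutree(hc, h = h)
  structure(list(hclust = hc, clusters = cl, distances = d, matrix = m,
                 pathway_subset = pathway_subset),
            class = "moa_clustering")
}

#' @export
print.moa_clustering <- function(x, ...) {
  cat("<moa_clustering> ", nrow(x$matrix), " drugs over ",
      length(x$pathway_subset), " pathway-direction columns; ",
      length(unique(x$clusters)), " flat clusters\n", sep = "")
  invisible(x)
}

#' Export a mode-of-action dendrogram as Newick
#'
#' @param clustering a [cluster_profiles()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export")
  }
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
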