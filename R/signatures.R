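#' Build a tibble of binary signatures
#'
#' A *signature* is a named finite set of string tokens owned by a compound
#' or a disease: fingerprint on-bit indices for structural (S) signatures,
#' gene identifiers for target (T) and expression (E) signatures. E
#' signatures carry a direction (`"up"`/`"down"`) and a cell-context label;
#' S and T signatures are undirected (`direction = "na"`).
#'
#' Gene identifiers are opaque strings: callers supply any consistent
#' namespace, which keeps synthetic and real data on one code path.
#'
#' @param owner_id character vector of compound or disease identifiers.
#' @param owner_kind `"compound"` or `"disease"` (recycled).
#' @param sig_type `"S"`, `"T"` or `"E"` (recycled).
#' @param direction `"up"`, `"down"`, `"combined"` or `"na"` (recycled).
#' @param context cell line / dataset label, `""` if not applicable.
#' @param features list of character vectors, one set per row.
#'
#' @return A tibble with one row per signature and a `features` list-column.
#' @export
#' @examples
#' signature_tbl("c1", "compound", "T", features = list(c("g1", "g2")))
signature_tbl <- function(owner_id, owner_kind = "compound", sig_type,
                          direction = NULL, context = "", features) {
  if (is.null(direction)) {
    direction <- ifelse(sig_type %in% c("S", "T"), "na", "combined")
  }
  tibble::tibble(
    owner_id = as.character(owner_id),
    owner_kind = owner_kind,
    sig_type = sig_type,
    direction = direction,
    context = as.character(context),
    features = lapply(features, function(x) unique(as.character(x)))
  )
}

sig_columns <- c("owner_id", "owner_kind", "sig_type", "direction",
                 "context", "features")

#' Validate a signature tibble
#'
#' Checks the structural invariants of the signature model and fails loudly
#' rather than repairing:
#' * every feature set is non-empty;
#' * S features parse as integers in `[0, fp_length)`;
#' * `direction == "na"` exactly for S and T rows;
#' * the up and down sets of the same (owner, context) E profile are
#'   disjoint.
#'
#' @param sigs a signature tibble as built by [signature_tbl()].
#' @param fp_length fingerprint length; S bit indices must lie in
#'   `[0, fp_length)`. Default 1024.
#'
#' @return `sigs`, invisibly, if valid; otherwise an error.
#' @export
validate_signatures <- function(sigs, fp_length = 1024) {
  missing_cols <- setdiff(sig_columns, names(sigs))
  if (length(missing_cols) > 0) {
    abort(paste0("signature table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  sizes <- lengths(sigs$features)
  if (any(sizes == 0)) {
    bad <- sigs$owner_id[sizes == 0][1]
    abort(paste0("empty feature set for owner '", bad, "'"))
  }
  bad_dir <- (sigs$sig_type %in% c("S", "T")) != (sigs$direction == "na")
  if (any(bad_dir)) {
    abort(paste0("direction must be 'na' exactly for S/T signatures ",
                 "(owner '", sigs$owner_id[bad_dir][1], "')"))
  }
  s_rows <- which(sigs$sig_type == "S")
  for (i in s_rows) {
    bits <- suppressWarnings(as.integer(sigs$features[[i]]))
    if (anyNA(bits) || any(bits < 0) || any(bits >= fp_length)) {
      abort(paste0("fingerprint bit index out of [0, ", fp_length,
                   ") for owner '", sigs$owner_id[i], "'"))
    }
  }
  e <- sigs[sigs$sig_type == "E" & sigs$direction %in% c("up", "down"), ]
  if (nrow(e) > 0) {
    key <- paste(e$owner_id, e$context, sep = "\r")
    for (k in unique(key)) {
      up <- unlist(e$features[key == k & e$direction == "up"])
      dn <- unlist(e$features[key == k & e$direction == "down"])
      if (length(intersect(up, dn)) > 0) {
        abort(paste0("up/down gene sets overlap for profile '",
                     sub("\r", " / ", k), "'"))
      }
    }
  }
  invisible(sigs)
}

#' Reduce signatures to one combined feature set per profile
#'
#' S and T rows each contribute their own set; the up and down rows of an E
#' profile (same owner and context) are merged into one presence/absence
#' set, matching the binary-vector view of a signature. With
#' `directional = TRUE`, E up and down rows are kept apart instead, for
#' direction-matched similarity.
#'
#' @param sigs signature tibble.
#' @param directional keep E up/down sets separate? Default `FALSE`.
#' @return A tibble with columns `owner_id`, `sig_type`, `direction`,
#'   `context`, `features`; for default reduction `direction` is
#'   `"combined"` for E rows.
#' @export
combine_signatures <- function(sigs, directional = FALSE) {
  st <- sigs[sigs$sig_type %in% c("S", "T"), sig_columns]
  e <- sigs[sigs$sig_type == "E", sig_columns]
  if (nrow(e) > 0 && !directional) {
    e <- e |>
      dplyr::group_by(.data$owner_id, .data$owner_kind, .data$sig_type,
                      .data$context) |>
      dplyr::summarise(
        features = list(unique(unlist(.data$features))),
        .groups = "drop"
      ) |>
      dplyr::mutate(direction = "combined")
    e <- e[, sig_columns]
  }
  dplyr::bind_rows(st, e)
}
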