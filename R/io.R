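#' Read a GMT gene-set file
#'
#' GMT is tab-separated: set id, description, then one member per field.
#' Duplicate members within a line are collapsed; duplicate set ids are an
#' error (they usually indicate unmerged compound identifiers upstream).
#'
#' @param path file path.
#' @return A tibble with columns `set_id`, `description` and a `genes`
#'   list-column, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(set_id = character(), description = character(),
                          genes = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(paste0("malformed GMT line ", bad[1], " in '", path,
                 "': fewer than 3 tab-separated fields"))
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate set_id in '", path, "': ",
                 paste(unique(dup), collapse = ", ")))
  }
  tibble::tibble(
    set_id = ids,
    description = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Write a GMT gene-set file
#'
#' @param records tibble with `set_id`, `description`, `genes` (list-column).
#' @param path output path.
#' @return `path`, invisibly. Round-trips through [read_gmt()] up to
#'   within-set ordering.
#' @export
write_gmt <- function(records, path) {
  if (anyDuplicated(records$set_id)) abort("duplicate set_id in GMT records")
  if (any(lengths(records$genes) == 0)) {
    abort("empty gene set cannot be written to GMT")
  }
  fields <- c(records$set_id, records$description,
              unlist(records$genes, use.names = FALSE))
  if (any(grepl("[\t\n]", fields))) {
    abort("GMT fields must not contain tab or newline characters")
  }
  lines <- mapply(function(id, desc, genes) {
    paste(c(id, desc, genes), collapse = "\t")
  }, records$set_id, records$description, records$genes)
  writeLines(as.character(lines), path)
  invisible(path)
}

#' Read structural fingerprints from TSV
#'
#' Two columns, no header: compound id and a comma-separated list of on-bit
#' indices. Fingerprints are consumed as precomputed on-bit sets (e.g. from
#' 1,024-bit FP2 hashing upstream); this package does no chemistry.
#'
#' @param path file path.
#' @param fp_length fingerprint length, default 1024.
#' @return A tibble with `compound_id` and a `bits` list-column of integer
#'   vectors.
#' @export
read_fingerprints <- function(path, fp_length = 1024) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_tsv(path, col_names = c("compound_id", "bits"),
                        col_types = "cc", progress = FALSE)
  if (anyDuplicated(df$compound_id)) {
    abort(paste0("duplicate compound rows in '", path, "': ",
                 df$compound_id[duplicated(df$compound_id)][1]))
  }
  bits <- lapply(strsplit(df$bits, ",", fixed = TRUE), function(x) {
    suppressWarnings(as.integer(x))
  })
  for (i in seq_along(bits)) {
    b <- bits[[i]]
    if (length(b) == 0 || anyNA(b)) {
      abort(paste0("compound '", df$compound_id[i],
                   "': fingerprint has no parseable on-bits"))
    }
    if (any(b < 0) || any(b >= fp_length)) {
      abort(paste0("compound '", df$compound_id[i],
                   "': bit index out of [0, ", fp_length, ")"))
    }
  }
  tibble::tibble(compound_id = df$compound_id,
                 bits = lapply(bits, function(b) sort(unique(b))))
}

#' Write fingerprints to TSV
#' @param fps tibble as returned by [read_fingerprints()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  if (any(lengths(fps$bits) == 0)) abort("fingerprint with zero on-bits")
  lines <- paste(fps$compound_id,
                 vapply(fps$bits, function(b) paste(sort(b), collapse = ","),
                        character(1)),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# Expression GMT lines use the id pattern "<compound>|<context>|<up|down>".
parse_expression_gmt <- function(gmt, owner_kind = "compound") {
  parts <- strsplit(gmt$set_id, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    abort(paste0("expression set id '", gmt$set_id[bad[1]],
                 "' does not match '<owner>|<context>|<up|down>'"))
  }
  dir <- vapply(parts, `[[`, character(1), 3)
  if (!all(dir %in% c("up", "down"))) {
    abort("expression set direction must be 'up' or 'down'")
  }
  signature_tbl(
    owner_id = vapply(parts, `[[`, character(1), 1),
    owner_kind = owner_kind,
    sig_type = "E",
    direction = dir,
    context = vapply(parts, `[[`, character(1), 2),
    features = gmt$genes
  )
}

format_expression_gmt <- function(sigs) {
  e <- sigs[sigs$sig_type == "E" & sigs$direction %in% c("up", "down"), ]
  tibble::tibble(
    set_id = paste(e$owner_id, e$context, e$direction, sep = "|"),
    description = e$owner_kind,
    genes = e$features
  )
}

#' Read the compound annotation table
#'
#' TSV with header columns `compound_id`, `name`, `fda_approved` (0/1) and
#' `bbb` (`yes`/`no`/`unknown`).
#' @param path file path.
#' @return A tibble with `compound_id`, `display_name`, `fda_approved`
#'   (logical), `bbb` (character).
#' @export
read_compound_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccic", progress = FALSE)
  need <- c("compound_id", "name", "fda_approved", "bbb")
  if (!all(need %in% names(df))) {
    abort(paste0("annotation table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df$compound_id)) abort("duplicate compound_id in annotations")
  if (!all(df$bbb %in% c("yes", "no", "unknown"))) {
    abort("bbb must be one of yes/no/unknown")
  }
  tibble::tibble(compound_id = df$compound_id, display_name = df$name,
                 fda_approved = df$fda_approved == 1, bbb = df$bbb)
}

#' Read HTS assay outcomes
#'
#' TSV with header columns `assay_id`, `compound_id`, `hit` (0/1); one row
#' per tested compound.
#' @param path file path.
#' @return A tibble with those columns, `hit` logical.
#' @export
read_hts_assays <- function(path) {
  df <- readr::read_tsv(path, col_types = "cci", progress = FALSE)
  need <- c("assay_id", "compound_id", "hit")
  if (!all(need %in% names(df))) {
    abort(paste0("assay table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df[c("assay_id", "compound_id")])) {
    abort("duplicate (assay_id, compound_id) rows in assay table")
  }
  dplyr::mutate(df, hit = .data$hit == 1)
}

read_id_list <- function(path) {
  if (is.null(path)) return(character())
  ids <- readLines(path, warn = FALSE)
  unique(ids[nzchar(ids)])
}

#' Assemble a compound-disease catalog
#'
#' The catalog bundles everything a repositioning run needs: the compound
#' table with FDA/BBB flags, all compound signatures, the disease reference
#' (known drugs, the wider cancer-drug set, disease expression signatures),
#' the pathway collection and the HTS assays.
#'
#' @param compounds tibble `compound_id`, `display_name`, `fda_approved`,
#'   `bbb`.
#' @param signatures compound signature tibble ([signature_tbl()]).
#' @param disease list with `disease_id`, `kd_ids`, `cd_ids`, `signatures`
#'   (disease E signature tibble); see [disease_reference()].
#' @param pathways optional [pathway_collection()].
#' @param assays optional HTS tibble ([read_hts_assays()] layout).
#' @param fp_length fingerprint length.
#' @return An object of class `dr_catalog`.
#' @export
dr_catalog <- function(compounds, signatures, disease, pathways = NULL,
                       assays = NULL, fp_length = 1024) {
  validate_signatures(signatures, fp_length = fp_length)
  if (anyDuplicated(compounds$compound_id)) {
    abort("duplicate compound_id in compound table")
  }
  known <- compounds$compound_id
  orphans <- setdiff(unique(signatures$owner_id), known)
  if (length(orphans) > 0) {
    abort(paste0("signatures for unknown compounds: ",
                 paste(head(orphans, 3), collapse = ", ")))
  }
  for (ids in list(disease$kd_ids, disease$cd_ids)) {
    missing <- setdiff(ids, known)
    if (length(missing) > 0) {
      abort(paste0("KD/CD list references unknown compound: ", missing[1]))
    }
  }
  if (!all(disease$kd_ids %in% disease$cd_ids)) {
    abort("KD set must be a subset of the CD set")
  }
  if (!is.null(assays)) {
    missing <- setdiff(unique(assays$compound_id), known)
    if (length(missing) > 0) {
      abort(paste0("assay references unknown compound: ", missing[1]))
    }
  }
  unsigned <- setdiff(known, unique(signatures$owner_id))
  structure(
    list(compounds = compounds, signatures = signatures, disease = disease,
         pathways = pathways, assays = assays, fp_length = fp_length,
         unsigned_ids = unsigned),
    class = "dr_catalog"
  )
}

#' @export
print.dr_catalog <- function(x, ...) {
  tab <- table(factor(x$signatures$sig_type, levels = c("S", "T", "E")))
  cat("<dr_catalog> ", nrow(x$compounds), " compounds; signatures: ",
      paste(names(tab), as.integer(tab), sep = "=", collapse = " "), "\n",
      sep = "")
  cat("  core set (S&T&E): ", length(core_set(x)), " compounds\n", sep = "")
  cat("  disease ", x$disease$disease_id, ": KD=",
      length(x$disease$kd_ids), " CD=", length(x$disease$cd_ids), "\n",
      sep = "")
  if (!is.null(x$pathways)) {
    cat("  pathways: ", length(x$pathways$pathways), " (universe ",
        length(x$pathways$universe), " genes)\n", sep = "")
  }
  if (!is.null(x$assays)) {
    cat("  assays: ", length(unique(x$assays$assay_id)), "\n", sep = "")
  }
  invisible(x)
}

#' Disease reference
#'
#' @param disease_id disease label.
#' @param kd_ids known drugs for this disease (the positive benchmark).
#' @param cd_ids compounds active against any cancer; must contain
#'   `kd_ids`. Excluded from the negative class.
#' @param signatures disease expression signature tibble (sig_type `"E"`,
#'   `owner_kind = "disease"`, one up/down pair per dataset).
#' @return A list of class `disease_reference`.
#' @export
disease_reference <- function(disease_id, kd_ids, cd_ids,
                              signatures = signature_tbl(
                                character(), "disease", character(),
                                features = list())) {
  if (!all(kd_ids %in% cd_ids)) abort("KD set must be a subset of the CD set")
  structure(list(disease_id = disease_id, kd_ids = unique(kd_ids),
                 cd_ids = unique(cd_ids), signatures = signatures),
            class = "disease_reference")
}

#' Pathway collection
#'
#' Pathway gene sets are intersected with the universe at load time;
#' pathways empty after intersection are dropped with a warning, and
#' pathways on the exclusion list (e.g. disease pathways redundant with
#' signalling pathways) are removed.
#'
#' @param pathways named list of gene-identifier character vectors.
#' @param universe the enrichment gene universe. If `NULL`, falls back to
#'   the union of all pathway genes (logged), but an explicit platform gene
#'   list is strongly preferred because the universe changes p-values
#'   materially.
#' @param excluded_ids pathway ids to drop.
#' @return A list of class `pathway_collection`.
#' @export
pathway_collection <- function(pathways, universe = NULL,
                               excluded_ids = character()) {
  if (is.null(universe)) {
    inform("pathway universe not supplied; using the union of pathway genes")
    universe <- unique(unlist(pathways))
  }
  universe <- unique(as.character(universe))
  pathways <- pathways[setdiff(names(pathways), excluded_ids)]
  pathways <- lapply(pathways, function(g) intersect(unique(g), universe))
  empty <- names(pathways)[lengths(pathways) == 0]
  if (length(empty) > 0) {
    warn(paste0("dropping ", length(empty),
                " pathway(s) empty after universe intersection: ",
                paste(head(empty, 3), collapse = ", ")))
    pathways <- pathways[lengths(pathways) > 0]
  }
  structure(list(pathways = pathways, universe = universe,
                 excluded_ids = excluded_ids),
            class = "pathway_collection")
}

#' The core compound set
#'
#' Compounds for which all three signature types (S, T, E) are available;
#' the unbiased evaluation universe. Invariant to file/row ordering.
#'
#' @param catalog a [dr_catalog()].
#' @return Sorted character vector of compound ids.
#' @export
core_set <- function(catalog) {
  tab <- catalog$signatures |>
    dplyr::distinct(.data$owner_id, .data$sig_type) |>
    dplyr::count(.data$owner_id)
  sort(tab$owner_id[tab$n == 3])
}

#' Load a catalog from a config file
#'
#' The YAML config names every input: `fingerprints`, `targets_gmt`,
#' `expression_gmt`, `annotations`, `disease` (`id`, `kd`, `cd`,
#' `signatures_gmt`), optionally `pathways` (`gmt`, `exclude`, `universe`)
#' and `assays`, plus `fp_length`. Relative paths resolve against the
#' config file's directory. Cross-references are resolved strictly:
#' referencing an unknown compound id is an error, but compounds that
#' appear only in the annotation table are retained with an empty
#' signature list (and listed in `catalog$unsigned_ids`).
#'
#' @param config path to a YAML config, or an equivalent named list.
#' @return A [dr_catalog()].
#' @export
load_catalog <- function(config) {
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  } else {
    base <- "."
  }
  pth <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  fp_length <- config$fp_length %||% 1024

  compounds <- read_compound_annotations(pth(config$annotations))
  fps <- read_fingerprints(pth(config$fingerprints), fp_length = fp_length)
  s_sigs <- signature_tbl(fps$compound_id, "compound", "S",
                          features = lapply(fps$bits, as.character))
  tg <- read_gmt(pth(config$targets_gmt))
  t_sigs <- signature_tbl(tg$set_id, "compound", "T", features = tg$genes)
  e_sigs <- parse_expression_gmt(read_gmt(pth(config$expression_gmt)))
  signatures <- dplyr::bind_rows(s_sigs, t_sigs, e_sigs)

  dis_cfg <- config$disease
  dis_sigs <- parse_expression_gmt(read_gmt(pth(dis_cfg$signatures_gmt)),
                                   owner_kind = "disease")
  disease <- disease_reference(
    disease_id = dis_cfg$id,
    kd_ids = read_id_list(pth(dis_cfg$kd)),
    cd_ids = read_id_list(pth(dis_cfg$cd)),
    signatures = dis_sigs
  )

  pathways <- NULL
  if (!is.null(config$pathways)) {
    pg <- read_gmt(pth(config$pathways$gmt))
    pw_list <- setNames(pg$genes, pg$set_id)
    universe <- if (!is.null(config$pathways$universe)) {
      read_id_list(pth(config$pathways$universe))
    }
    pathways <- pathway_collection(
      pw_list, universe = universe,
      excluded_ids = read_id_list(pth(config$pathways$exclude))
    )
  }

  assays <- if (!is.null(config$assays)) read_hts_assays(pth(config$assays))

  cat <- dr_catalog(compounds, signatures, disease, pathways = pathways,
                    assays = assays, fp_length = fp_length)
  if (length(cat$unsigned_ids) > 0) {
    inform(paste0(length(cat$unsigned_ids),
                  " compound(s) carry no signatures and are retained ",
                  "outside the core set"))
  }
  cat
}
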