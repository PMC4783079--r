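#' A tiny hand-checkable repositioning world
#'
#' Six compounds, a 20-gene universe and 16-bit fingerprints — small
#' enough that every Tanimoto coefficient, association feature and
#' hypergeometric p-value can be recomputed by hand. Constructed
#' literally (no randomness). The layout exercises each pipeline rule:
#' `c1` is the sole known drug (two expression contexts), `c2` is CD but
#' not KD, `c3` is a structural analog of both CD members, `c4` is
#' related to neither, and `c6` lacks a target signature and so falls
#' outside the core set. The bundled assay marks `c1`-`c4` as hits, so
#' the hit partition is one known-excluded, one anti-cancer by CD
#' membership, one anti-cancer by analogs and one novel hit.
#'
#' Reference tables for this fixture, computed by an independent
#' brute-force oracle, ship under
#' `system.file("extdata/worked_example", package = "drsig")`.
#'
#' @return A [dr_catalog()] with pathways and one assay; `fp_length` 16.
#' @export
generate_worked_example <- function() {
  fp_bits <- list(
    c1 = 0:7,
    c2 = c(0:6, 8),
    c3 = c(0:6, 9),
    c4 = c(0:4, 8:10),
    c5 = 8:15,
    c6 = 4:11
  )
  targets <- list(
    c1 = c("g01", "g02"),
    c2 = c("g02", "g03"),
    c3 = c("g01", "g03"),
    c4 = c("g04", "g05"),
    c5 = "g05"
  )
  e_sets <- tibble::tribble(
    ~owner, ~context, ~up, ~down,
    "c1", "ctxA", c("g01", "g02", "g04"), c("g11", "g14", "g15"),
    "c1", "ctxB", c("g01", "g03", "g05"), c("g12", "g14", "g16"),
    "c2", "ctxA", c("g02", "g03", "g06"), c("g11", "g12", "g17"),
    "c3", "ctxA", c("g01", "g06", "g07"), c("g13", "g18", "g19"),
    "c4", "ctxA", c("g04", "g06", "g08"), c("g15", "g17", "g20"),
    "c5", "ctxA", c("g05", "g07", "g09"), c("g16", "g18", "g20"),
    "c6", "ctxA", c("g02", "g08", "g09"), c("g13", "g19", "g20")
  )
  signatures <- dplyr::bind_rows(
    signature_tbl(names(fp_bits), "compound", "S",
                  features = lapply(fp_bits, as.character)),
    signature_tbl(names(targets), "compound", "T", features = targets),
    signature_tbl(e_sets$owner, "compound", "E", "up",
                  context = e_sets$context, features = e_sets$up),
    signature_tbl(e_sets$owner, "compound", "E", "down",
                  context = e_sets$context, features = e_sets$down)
  )
  compounds <- tibble::tibble(
    compound_id = paste0("c", 1:6),
    display_name = paste0("example-", 1:6),
    fda_approved = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    bbb = c("yes", "unknown", "no", "yes", "no", "unknown")
  )
  disease <- disease_reference(
    "toy_disease", kd_ids = "c1", cd_ids = c("c1", "c2"),
    signatures = signature_tbl(
      c("toy_disease", "toy_disease"), "disease", "E", c("up", "down"),
      context = "dataset1",
      features = list(c("g01", "g02", "g03"), c("g11", "g12", "g13"))
    )
  )
  pathways <- pathway_collection(
    list(pwA = c("g01", "g02", "g03", "g04"),
         pwB = c("g11", "g12", "g13", "g14"),
         pwC = c("g05", "g06", "g07", "g08", "g09", "g10")),
    universe = sprintf("g%02d", 1:20)
  )
  assay <- tibble::tibble(
    assay_id = "toy_assay",
    compound_id = paste0("c", 1:6),
    hit = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  dr_catalog(compounds, signatures, disease, pathways = pathways,
             assays = assay, fp_length = 16)
}
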