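# Scaled-down world parameters for fast unit tests; acceptance checks use
# the full defaults.
tiny_params <- function(seed = 1, ...) {
  world_params(n_compounds = 60, n_active = 15, n_kd = 5, n_cd_extra = 5,
               gene_universe_size = 600, e_sig_size = 30,
               disease_gene_pool = 90, t_pool_size = 30, n_pathways = 20,
               pathway_size = 15, n_scaffolds = 8, fp_length = 256,
               fp_on_bits = 40, n_moa_groups = 2, moa_drugs_per_group = 3,
               seed = seed, ...)
}

tiny_world <- function(seed = 1, ...) generate_world(tiny_params(seed, ...))

# Minimal catalog where every compound has one S, one T and one E profile;
# used for benchmark-label and rule tests.
mini_catalog <- function(ids, kd, cd, fp_sets = NULL, skip_t = character()) {
  n <- length(ids)
  fp_sets <- fp_sets %||% lapply(seq_len(n), function(i) {
    as.character((2 * i):(2 * i + 3))
  })
  genes_up <- lapply(seq_len(n), function(i) paste0("u", i, "_", 1:3))
  genes_dn <- lapply(seq_len(n), function(i) paste0("d", i, "_", 1:3))
  t_ids <- setdiff(ids, skip_t)
  sigs <- dplyr::bind_rows(
    signature_tbl(ids, "compound", "S",
                  features = lapply(fp_sets, as.character)),
    signature_tbl(t_ids, "compound", "T",
                  features = lapply(seq_along(t_ids),
                                    function(i) paste0("t", i))),
    signature_tbl(ids, "compound", "E", "up", context = "cx",
                  features = genes_up),
    signature_tbl(ids, "compound", "E", "down", context = "cx",
                  features = genes_dn)
  )
  compounds <- tibble::tibble(compound_id = ids, display_name = ids,
                              fda_approved = TRUE, bbb = "yes")
  disease <- disease_reference(
    "d1", kd_ids = kd, cd_ids = cd,
    signatures = signature_tbl(c("d1", "d1"), "disease", "E",
                               c("up", "down"), context = "ds1",
                               features = list(c("u1_1", "u1_2"),
                                               c("d1_1", "d1_2")))
  )
  dr_catalog(compounds, sigs, disease, fp_length = 1024)
}

# Stored worked-example reference tables (independent brute-force oracle).
worked_example_table <- function(name) {
  path <- system.file("extdata", "worked_example", name, package = "drsig")
  if (!nzchar(path)) {
    path <- file.path(testthat::test_path(), "..", "..", "inst", "extdata",
                      "worked_example", name)
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
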