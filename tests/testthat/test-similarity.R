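test_that("tanimoto matches hand counts and is symmetric", {
  expect_equal(tanimoto(c("g1", "g2", "g3"), c("g1", "g2", "g3")), 1)
  expect_equal(tanimoto("g1", "g2"), 0)
  expect_equal(tanimoto(c("g1", "g2", "g3"), c("g2", "g3", "g4")), 0.5)
  expect_error(tanimoto(character(), character()), "undefined")
  withr::local_seed(21)
  for (i in 1:20) {
    a <- random_set(paste0("x", 1:40), 15)
    b <- random_set(paste0("x", 1:40), 15)
    expect_identical(tanimoto(a, b), tanimoto(b, a))
  }
})

test_that("mean pairwise similarity is the flat mean over all pairs", {
  # single pair reduces to tanimoto
  expect_equal(mean_pairwise_similarity(list(c("a", "b")), list(c("b", "c"))),
               tanimoto(c("a", "b"), c("b", "c")))
  # pairs at 1.0 and 0.0 average to 0.5
  expect_equal(
    mean_pairwise_similarity(list(c("a", "b")),
                             list(c("a", "b"), c("x", "y"))),
    0.5
  )
  # duplicating the compound signature does not move a mean of equal values
  expect_equal(
    mean_pairwise_similarity(list(c("a", "b"), c("a", "b")), list("a")),
    mean_pairwise_similarity(list(c("a", "b")), list("a"))
  )
  expect_true(is.na(mean_pairwise_similarity(list(), list("a"))))
})

test_that("feature builder handles self-similarity and missing channels", {
  cat <- mini_catalog(c("a", "b", "c"), kd = "a", cd = "a", skip_t = "c")
  f <- build_association_features(cat)
  # the sole known drug scored against itself
  expect_equal(f$S_S[f$compound_id == "a"], 1)
  expect_equal(f$T_T[f$compound_id == "a"], 1)
  expect_equal(f$E_Ekd[f$compound_id == "a"], 1)
  # compound without a T signature: all T_* features missing, others not
  row_c <- f[f$compound_id == "c", ]
  expect_true(all(is.na(c(row_c$T_T, row_c$T_Ekd, row_c$T_Edis))))
  expect_false(anyNA(c(row_c$S_S, row_c$E_Ekd, row_c$E_Edis)))
  expect_error(build_association_features(cat, features = "bogus"),
               "unknown feature")
})

test_that("features match the brute-force oracle on random small worlds", {
  withr::local_seed(31)
  for (rep in 1:4) {
    w <- tiny_world(seed = 100 + rep)
    ids <- sample(w$catalog$compounds$compound_id, 12)
    keep <- w$catalog
    got <- build_association_features(keep, compound_ids = ids)
    want <- bf_features(keep)
    want <- want[match(ids, want$compound_id), ]
    for (f in dr_feature_names()) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12, label = f)
    }
  }
})

test_that("features are invariant to ordering of rows and set members", {
  w <- tiny_world(seed = 9)
  base <- build_association_features(w$catalog)
  shuf <- w$catalog
  withr::with_seed(77, {
    shuf$signatures <- shuf$signatures[sample(nrow(shuf$signatures)), ]
    shuf$signatures$features <- lapply(shuf$signatures$features, sample)
    shuf$compounds <- shuf$compounds[sample(nrow(shuf$compounds)), ]
  })
  again <- build_association_features(shuf)
  again <- again[match(base$compound_id, again$compound_id), ]
  expect_equal(as.data.frame(again), as.data.frame(base),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("growing overlap with every KD expression signature raises E_Ekd", {
  # hold set sizes fixed; swap background genes for KD-shared genes
  kd_genes <- paste0("k", 1:6)
  make_cat <- function(overlap) {
    probe_up <- c(kd_genes[seq_len(overlap)],
                  paste0("b", seq_len(3 - overlap)))
    sigs <- dplyr::bind_rows(
      signature_tbl("kd1", "compound", "S", features = list("1")),
      signature_tbl("kd1", "compound", "T", features = list("t1")),
      signature_tbl("kd1", "compound", "E", "up", "cx",
                    features = list(kd_genes[1:3])),
      signature_tbl("kd1", "compound", "E", "down", "cx",
                    features = list(kd_genes[4:6])),
      signature_tbl("p", "compound", "S", features = list("2")),
      signature_tbl("p", "compound", "E", "up", "cx",
                    features = list(probe_up)),
      signature_tbl("p", "compound", "E", "down", "cx",
                    features = list(paste0("c", 1:3)))
    )
    compounds <- tibble::tibble(compound_id = c("kd1", "p"),
                                display_name = c("kd1", "p"),
                                fda_approved = TRUE, bbb = "yes")
    dr_catalog(compounds, sigs,
               disease_reference("d", "kd1", "kd1"))
  }
  vals <- vapply(0:3, function(k) {
    f <- build_association_features(make_cat(k), features = "E_Ekd")
    f$E_Ekd[f$compound_id == "p"]
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_gt(vals[4], vals[1])
})

test_that("leave-self-out pools equal full pools built without the compound", {
  w <- tiny_world(seed = 13)
  kd <- w$catalog$disease$kd_ids
  loo <- build_association_features(w$catalog, loo_kd = TRUE)
  full <- build_association_features(w$catalog)
  target <- kd[1]
  # manual: drop target's signatures from the catalog's KD pool entirely
  stripped <- w$catalog
  stripped$disease$kd_ids <- setdiff(kd, target)
  manual <- build_association_features(stripped, compound_ids = target)
  got <- loo[loo$compound_id == target, dr_feature_names()]
  expect_equal(as.data.frame(got),
               as.data.frame(manual[, dr_feature_names()]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # non-KD rows are untouched by the guard
  other <- setdiff(loo$compound_id, kd)
  expect_equal(loo[loo$compound_id %in% other, ],
               full[full$compound_id %in% other, ])
})

test_that("directional similarity averages up-up and down-down channels", {
  sigs <- dplyr::bind_rows(
    signature_tbl("kd1", "compound", "S", features = list("1")),
    signature_tbl("kd1", "compound", "E", "up", "cx",
                  features = list(c("u1", "u2"))),
    signature_tbl("kd1", "compound", "E", "down", "cx",
                  features = list(c("d1", "d2"))),
    signature_tbl("p", "compound", "S", features = list("2")),
    # matches kd1's up genes but in the DOWN direction
    signature_tbl("p", "compound", "E", "up", "cx",
                  features = list(c("x1", "x2"))),
    signature_tbl("p", "compound", "E", "down", "cx",
                  features = list(c("u1", "u2")))
  )
  compounds <- tibble::tibble(compound_id = c("kd1", "p"),
                              display_name = c("kd1", "p"),
                              fda_approved = TRUE, bbb = "yes")
  cat <- dr_catalog(compounds, sigs, disease_reference("d", "kd1", "kd1"))
  undirected <- build_association_features(cat, features = "E_Ekd")
  directed <- build_association_features(cat, features = "E_Ekd",
                                         directional = TRUE)
  # presence/absence union sees the shared genes; direction-matched does not
  expect_gt(undirected$E_Ekd[undirected$compound_id == "p"], 0)
  expect_equal(directed$E_Ekd[directed$compound_id == "p"], 0)
})
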