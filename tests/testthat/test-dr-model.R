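test_that("benchmark labels partition the core set by KD/CD rules", {
  cat <- mini_catalog(c("a", "b", "c"), kd = "a", cd = c("a", "b"))
  lab <- suppressMessages(make_benchmark(cat))
  expect_equal(lab$positives, "a")
  expect_equal(lab$negatives, "c")
  expect_equal(lab$ambiguous, "b")
  expect_setequal(c(lab$positives, lab$negatives, lab$ambiguous), lab$core)

  # CD = KD leaves no ambiguous compounds
  lab2 <- suppressMessages(
    make_benchmark(mini_catalog(c("a", "b"), kd = "a", cd = "a")))
  expect_equal(lab2$ambiguous, character())

  # core contained in CD: no negatives
  expect_error(
    suppressMessages(
      make_benchmark(mini_catalog(c("a", "b"), kd = "a", cd = c("a", "b")))),
    "no negatives"
  )
})

test_that("separated single-feature data yields near-certain scores", {
  feats <- tibble::tibble(
    compound_id = paste0("c", 1:20), disease_id = "d",
    E_T = rep(c(1, 0), each = 10), E_Ekd = rep(c(1, 0), each = 10),
    E_Edis = rep(c(1, 0), each = 10)
  )
  lab <- structure(list(positives = paste0("c", 1:10),
                        negatives = paste0("c", 11:20),
                        ambiguous = character()),
                   class = "dr_benchmark")
  expect_warning(m <- fit_dr_model(feats, lab, "E"), "separation")
  sc <- dr_score(m, feats)
  expect_true(all(sc$dr_score[1:10] > 0.99))
  expect_true(all(sc$dr_score[11:20] < 0.01))
})

test_that("duplicating every row preserves the decision ordering", {
  # the likelihood is invariant under row duplication, so the MLE and
  # scores are unchanged; overlapping classes keep the fit well-posed
  withr::local_seed(64)
  n <- 40
  f <- tibble::tibble(compound_id = paste0("c", 1:n),
                      S_S = c(runif(n / 2, 0.2, 0.9),
                              runif(n / 2, 0.1, 0.8)))
  lab <- structure(list(positives = paste0("c", 1:(n / 2)),
                        negatives = paste0("c", (n / 2 + 1):n),
                        ambiguous = character()),
                   class = "dr_benchmark")
  m1 <- fit_dr_model(f, lab, "S")
  expect_false(m1$separation)
  doubled <- dplyr::bind_rows(
    f, dplyr::mutate(f, compound_id = paste0(.data$compound_id, "_dup")))
  lab2 <- lab
  lab2$positives <- c(lab$positives, paste0(lab$positives, "_dup"))
  lab2$negatives <- c(lab$negatives, paste0(lab$negatives, "_dup"))
  m2 <- fit_dr_model(doubled, lab2, "S")
  s1 <- dr_score(m1, f)
  s2 <- dr_score(m2, f)
  expect_equal(s1$dr_score, s2$dr_score, tolerance = 1e-6)
})

test_that("dr_score is the inverse logit of the linear predictor", {
  model <- structure(
    list(classifier = "S", feature_names = "S_S",
         coefficients = c(`(Intercept)` = -1, S_S = 2)),
    class = "dr_model"
  )
  feats <- tibble::tibble(compound_id = c("a", "b", "c"),
                          S_S = c(0.5, 100, NA))
  sc <- suppressMessages(dr_score(model, feats))
  expect_equal(sc$dr_score[sc$compound_id == "a"], 0.5)
  expect_gt(sc$dr_score[sc$compound_id == "b"], 1 - 1e-10)
  expect_false("c" %in% sc$compound_id)
  expect_equal(attr(sc, "skipped"), "c")
})

test_that("percentile ranks follow the empirical CDF with max-tie sharing", {
  four <- tibble::tibble(compound_id = letters[1:4],
                         dr_score = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(sort(percentile_rank(four)$percentile),
               c(0.25, 0.5, 0.75, 1))
  tied <- tibble::tibble(compound_id = letters[1:3], dr_score = 0.7)
  expect_equal(percentile_rank(tied)$percentile, rep(1, 3))
  one <- tibble::tibble(compound_id = "a", dr_score = 0.1)
  expect_equal(percentile_rank(one)$percentile, 1)
})

test_that("roc_auc matches the pair-counting definition", {
  sc <- setNames(c(0.9, 0.8, 0.7, 0.6), c("p1", "n1", "p2", "n2"))
  expect_equal(roc_auc(sc, c("p1", "p2"), c("n1", "n2")), 0.75)
  expect_equal(roc_auc(setNames(c(1, 1), c("p", "n")), "p", "n"), 0.5)
  expect_equal(roc_auc(setNames(c(0.9, 0.1), c("p", "n")), "p", "n"), 1)
  expect_error(roc_auc(sc, character(), "n1"), "positive")
})

test_that("rank-based outputs are invariant to monotone score transforms", {
  withr::local_seed(8)
  sc <- tibble::tibble(compound_id = paste0("c", 1:30),
                       dr_score = runif(30))
  squashed <- dplyr::mutate(sc, dr_score = plogis(5 * .data$dr_score - 2))
  pos <- paste0("c", 1:10)
  neg <- paste0("c", 11:30)
  expect_equal(roc_auc(sc, pos, neg), roc_auc(squashed, pos, neg))
  expect_equal(percentile_rank(sc)$percentile,
               percentile_rank(squashed)$percentile)
})

test_that("cross-validation is seeded, prefix-consistent and null-calibrated", {
  w <- tiny_world(seed = 6)
  f <- build_association_features(w$catalog, loo_kd = TRUE)
  lab <- suppressMessages(make_benchmark(w$catalog))
  cv1 <- cross_validate(f, lab, "E", rounds = 1, seed = 99)
  cv10 <- cross_validate(f, lab, "E", rounds = 10, seed = 99)
  expect_identical(cv1$round_aucs[1], cv10$round_aucs[1])
  cv10b <- cross_validate(f, lab, "E", rounds = 10, seed = 99)
  expect_identical(cv10$round_aucs, cv10b$round_aucs)

  # permuted labels destroy the signal
  withr::with_seed(15, {
    pool <- c(lab$positives, lab$negatives)
    fake_pos <- sample(pool, length(lab$positives))
  })
  perm <- structure(list(positives = fake_pos,
                         negatives = setdiff(pool, fake_pos),
                         ambiguous = lab$ambiguous),
                    class = "dr_benchmark")
  cv_null <- suppressWarnings(
    cross_validate(f, perm, "E", rounds = 30, seed = 7))
  expect_gt(cv_null$mean_auc, 0.3)
  expect_lt(cv_null$mean_auc, 0.7)
})

test_that("tidy and glance expose classifier fits and CV runs", {
  w <- tiny_world(seed = 2)
  f <- build_association_features(w$catalog)
  lab <- suppressMessages(make_benchmark(w$catalog))
  m <- fit_dr_model(f, lab, "TE")
  td <- tidy(m)
  expect_equal(td$term,
               c("(Intercept)", classifier_features("TE")))
  gl <- glance(m)
  expect_equal(gl$classifier, "TE")
  cv <- cross_validate(f, lab, "S", rounds = 3, seed = 1)
  expect_equal(nrow(tidy(cv)), 3)
  expect_equal(glance(cv)$mean_auc, mean(cv$round_aucs))
})

test_that("candidate filter applies FDA, strict threshold and BBB flag", {
  ranks <- tibble::tibble(
    compound_id = c("top", "edge", "unapproved", "low"),
    dr_score = c(0.98, 0.93, 0.99, 0.2),
    percentile = c(0.98, 0.90, 0.99, 0.30)
  )
  compounds <- tibble::tibble(
    compound_id = c("top", "edge", "unapproved", "low"),
    display_name = c("top", "edge", "unapproved", "low"),
    fda_approved = c(TRUE, TRUE, FALSE, TRUE),
    bbb = c("no", "yes", "yes", "yes")
  )
  cat <- list(compounds = compounds)
  out <- filter_candidates(ranks, cat, threshold = 0.9)
  # high scorer kept despite bbb = no, but flagged
  expect_equal(out$compound_id, "top")
  expect_true(out$bbb_warning)
  # exactly at the threshold is excluded (strict >), as is non-FDA
  expect_false("edge" %in% out$compound_id)
  expect_false("unapproved" %in% out$compound_id)
})

test_that("classifier feature subsets are the declared unions", {
  expect_equal(classifier_features("S"), "S_S")
  expect_equal(classifier_features("TE"),
               c("T_T", "T_Ekd", "T_Edis", "E_T", "E_Ekd", "E_Edis"))
  expect_setequal(classifier_features("STE"), dr_feature_names())
  expect_error(classifier_features("X"))
})
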