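#' Feature subsets of the seven classifiers
#'
#' The classifier family compares the three signature channels: single
#' channels (`S`, `T`, `E`), pairs (`ST`, `SE`, `TE`) and all three
#' (`STE`). The S channel contributes `S_S`; the T channel `T_T`, `T_Ekd`,
#' `T_Edis`; the E channel `E_T`, `E_Ekd`, `E_Edis`; combinations take
#' unions.
#'
#' @param name one of `"S","T","E","ST","SE","TE","STE"`.
#' @return Character vector of feature names.
#' @export
classifier_features <- function(name) {
  name <- match.arg(name, dr_classifier_names())
  blocks <- list(S = "S_S", T = c("T_T", "T_Ekd", "T_Edis"),
                 E = c("E_T", "E_Ekd", "E_Edis"))
  unlist(blocks[strsplit(name, "")[[1]]], use.names = FALSE)
}

#' @rdname classifier_features
#' @export
dr_classifier_names <- function() c("S", "T", "E", "ST", "SE", "TE", "STE")

#' Construct benchmark labels from the catalog
#'
#' The positive class is the disease's known drugs restricted to the core
#' set; the negative class is the core set minus the full cancer-active
#' (CD) set; CD compounds that are not known drugs are "ambiguous" and
#' excluded from both classes (they still receive scores at prediction
#' time). The three sets partition the core set.
#'
#' @param catalog a [dr_catalog()].
#' @return A list of class `dr_benchmark` with `positives`, `negatives`,
#'   `ambiguous` (character vectors) and `core` (the core set).
#' @export
make_benchmark <- function(catalog) {
  core <- core_set(catalog)
  if (length(core) == 0) abort("core set is empty")
  positives <- sort(intersect(catalog$disease$kd_ids, core))
  ambiguous <- sort(intersect(setdiff(catalog$disease$cd_ids,
                                      catalog$disease$kd_ids), core))
  negatives <- sort(setdiff(core, catalog$disease$cd_ids))
  if (length(positives) == 0) abort("no known drugs in the core set")
  if (length(negatives) == 0) {
    abort("no negatives: the core set is contained in the CD set")
  }
  inform(paste0("benchmark: ", length(positives), " positives, ",
                length(negatives), " negatives, ", length(ambiguous),
                " ambiguous (of ", length(core), " core compounds)"))
  structure(list(positives = positives, negatives = negatives,
                 ambiguous = ambiguous, core = core),
            class = "dr_benchmark")
}

# Newton-Raphson ridge logistic regression; penalty lambda on slopes only.
# Used directly for the separation fallback and as the engine checkline.
ridge_logistic <- function(x, y, lambda, tol = 1e-8, max_iter = 1000) {
  x1 <- cbind(`(Intercept)` = 1, x)
  p <- ncol(x1)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (i in seq_len(max_iter)) {
    eta <- drop(x1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(x1, y - mu)) - drop(pen %*% beta)
    hess <- crossprod(x1 * w, x1) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  setNames(drop(beta), colnames(x1))
}

#' Fit a DR classifier
#'
#' Unregularised maximum-likelihood logistic regression of known-drug
#' status on the classifier's association features. Complete separation
#' (or non-convergence) triggers a weak-L2 ridge refit with a logged
#' warning; with at most seven bounded features this is rare. Rows with
#' any missing model feature are dropped with a logged count.
#'
#' @param features association feature tibble
#'   ([build_association_features()]).
#' @param labels a `dr_benchmark` from [make_benchmark()].
#' @param classifier classifier name, see [dr_classifier_names()].
#' @param ridge L2 strength for the separation fallback. Default `1e-4`.
#' @return An object of class `dr_model` with elements `classifier`,
#'   `feature_names`, `coefficients` (named, intercept first),
#'   `training_ids`, `n_dropped`, `separation`.
#' @export
fit_dr_model <- function(features, labels, classifier = "STE",
                         ridge = 1e-4) {
  fn <- classifier_features(classifier)
  dat <- dplyr::filter(features,
                       .data$compound_id %in% c(labels$positives,
                                                labels$negatives))
  y <- as.numeric(dat$compound_id %in% labels$positives)
  x <- as.matrix(dat[, fn, drop = FALSE])
  ok <- stats::complete.cases(x)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(paste0("fit_dr_model: dropping ", n_dropped,
                  " row(s) with missing features"))
  }
  x <- x[ok, , drop = FALSE]
  y <- y[ok]
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    abort("need at least 2 compounds per class to fit")
  }
  fit <- suppressWarnings(
    glm.fit(cbind(`(Intercept)` = 1, x), y, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 1000))
  )
  mu <- fit$fitted.values
  separated <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8) ||
    any(abs(fit$coefficients[-1]) > 1e3, na.rm = TRUE)
  if (separated) {
    warn(paste0("separation detected for classifier ", classifier,
                "; refitting with L2 strength ", ridge))
    coefs <- ridge_logistic(x, y, lambda = ridge)
  } else {
    coefs <- fit$coefficients
    # aliased (e.g. constant) columns contribute nothing, not NA scores
    coefs[is.na(coefs)] <- 0
  }
  structure(
    list(classifier = classifier, feature_names = fn,
         coefficients = coefs, training_ids = dat$compound_id[ok],
         n_dropped = n_dropped, separation = separated,
         n_pos = sum(y == 1), n_neg = sum(y == 0)),
    class = "dr_model"
  )
}

#' @export
print.dr_model <- function(x, ...) {
  cat("<dr_model> classifier ", x$classifier, " (",
      x$n_pos, " pos / ", x$n_neg, " neg",
      if (x$separation) "; ridge fallback", ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
#' @method tidy dr_model
tidy.dr_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
#' @method glance dr_model
glance.dr_model <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, n_pos = x$n_pos,
                 n_neg = x$n_neg, n_dropped = x$n_dropped,
                 separation = x$separation)
}

#' DR scores for a feature table
#'
#' The DR score is the inverse-logit of the fitted linear predictor, a
#' probability-scaled repositioning score in (0, 1). Compounds missing any
#' model feature are skipped and reported via the `skipped` attribute.
#'
#' @param model a [fit_dr_model()] object.
#' @param features association feature tibble.
#' @return A tibble `compound_id`, `dr_score`, ordered as `features`.
#' @export
dr_score <- function(model, features) {
  x <- as.matrix(features[, model$feature_names, drop = FALSE])
  ok <- stats::complete.cases(x)
  if (any(!ok)) {
    inform(paste0("dr_score: skipping ", sum(!ok),
                  " compound(s) with missing features"))
  }
  eta <- drop(cbind(1, x[ok, , drop = FALSE]) %*% model$coefficients)
  out <- tibble::tibble(compound_id = features$compound_id[ok],
                        dr_score = plogis(eta))
  attr(out, "skipped") <- features$compound_id[!ok]
  out
}

#' Percentile ranks of DR scores
#'
#' `rank(c) = #\{score <= score(c)\} / n`: the empirical CDF evaluated at
#' each score. Ties share a rank and the maximum-scoring compound always
#' has rank 1.
#'
#' @param scores tibble with `compound_id` and `dr_score`.
#' @return The input with a `percentile` column in (0, 1].
#' @export
percentile_rank <- function(scores) {
  if (nrow(scores) == 0) abort("no scores to rank")
  dplyr::mutate(scores,
                percentile = rank(.data$dr_score, ties.method = "max") /
                  dplyr::n())
}

#' ROC AUC by the Mann-Whitney pair formulation
#'
#' The fraction of (positive, negative) pairs in which the positive scores
#' strictly higher, ties counted 1/2.
#'
#' @param scores tibble with `compound_id`, `dr_score` (or a named numeric
#'   vector).
#' @param positives,negatives character vectors of compound ids; ids
#'   without scores are ignored.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positives, negatives) {
  if (is.data.frame(scores)) {
    scores <- setNames(scores$dr_score, scores$compound_id)
  }
  sp <- scores[names(scores) %in% positives]
  sn <- scores[names(scores) %in% negatives]
  if (length(sp) == 0 || length(sn) == 0) {
    abort("roc_auc needs at least one scored positive and one negative")
  }
  r <- rank(c(sp, sn), ties.method = "average")
  (sum(r[seq_along(sp)]) - length(sp) * (length(sp) + 1) / 2) /
    (length(sp) * length(sn))
}

# Stratified fold assignment; re-drawn (rarely) if a fold lacks a class.
stratified_folds <- function(pos_n, neg_n, folds) {
  repeat {
    fp <- sample(rep_len(seq_len(folds), pos_n))
    fn <- sample(rep_len(seq_len(folds), neg_n))
    ok <- all(tabulate(fp, folds) > 0) && all(tabulate(fn, folds) > 0)
    if (ok) return(list(pos = fp, neg = fn))
  }
}

#' Repeated stratified cross-validation of a DR classifier
#'
#' Each round draws a stratified random partition of the labelled
#' compounds into `folds` folds, fits on all but one fold, scores the
#' held-out fold, pools the round's held-out scores and computes a single
#' AUC; the summary is the mean over rounds. Pass a feature table built
#' with `loo_kd = TRUE` so that known drugs are scored against reference
#' pools that exclude their own signatures (leakage guard).
#'
#' @param features association feature tibble (leave-self-out features for
#'   KD compounds recommended; see [build_association_features()]).
#' @param labels `dr_benchmark`.
#' @param classifier classifier name.
#' @param rounds number of repeats, default 100.
#' @param folds number of folds, default 3.
#' @param seed integer seed; the per-round AUC vector is reproducible
#'   bit-for-bit for a fixed seed.
#' @param ridge separation-fallback L2 strength.
#' @return An object of class `dr_cv`: list with `classifier`,
#'   `mean_auc`, `round_aucs` (length `rounds`), `rounds`, `folds`,
#'   `seed`.
#' @export
cross_validate <- function(features, labels, classifier = "STE",
                           rounds = 100, folds = 3, seed = 1,
                           ridge = 1e-4) {
  fn <- classifier_features(classifier)
  dat <- dplyr::filter(features,
                       .data$compound_id %in% c(labels$positives,
                                                labels$negatives))
  x <- as.matrix(dat[, fn, drop = FALSE])
  ok <- stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]
  id <- dat$compound_id[ok]
  y <- as.numeric(id %in% labels$positives)
  ip <- which(y == 1)
  ineg <- which(y == 0)
  if (length(ip) < folds || length(ineg) < folds) {
    abort("each class must have at least `folds` members")
  }
  x1 <- cbind(`(Intercept)` = 1, x)

  round_aucs <- withr::with_seed(seed, {
    vapply(seq_len(rounds), function(r) {
      fa <- stratified_folds(length(ip), length(ineg), folds)
      held <- numeric(length(y))
      for (f in seq_len(folds)) {
        test <- c(ip[fa$pos == f], ineg[fa$neg == f])
        train <- setdiff(seq_along(y), test)
        fit <- suppressWarnings(
          glm.fit(x1[train, , drop = FALSE], y[train], family = binomial(),
                  control = list(epsilon = 1e-8, maxit = 1000))
        )
        mu <- fit$fitted.values
        if (!fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)) {
          beta <- ridge_logistic(x[train, , drop = FALSE], y[train],
                                 lambda = ridge)
        } else {
          beta <- fit$coefficients
          beta[is.na(beta)] <- 0
        }
        held[test] <- drop(x1[test, , drop = FALSE] %*% beta)
      }
      sc <- setNames(held, id)
      roc_auc(sc, id[y == 1], id[y == 0])
    }, numeric(1))
  })
  structure(list(classifier = classifier, mean_auc = mean(round_aucs),
                 round_aucs = round_aucs, rounds = rounds, folds = folds,
                 seed = seed),
            class = "dr_cv")
}

#' @export
print.dr_cv <- function(x, ...) {
  cat("<dr_cv> classifier ", x$classifier, ": mean AUC ",
      sprintf("%.3f", x$mean_auc), " over ", x$rounds, " rounds of ",
      x$folds, "-fold CV\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy dr_cv
tidy.dr_cv <- function(x, ...) {
  tibble::tibble(classifier = x$classifier,
                 round = seq_along(x$round_aucs), auc = x$round_aucs)
}

#' @export
#' @method glance dr_cv
glance.dr_cv <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, mean_auc = x$mean_auc,
                 sd_auc = stats::sd(x$round_aucs), rounds = x$rounds,
                 folds = x$folds, seed = x$seed)
}

#' Cross-validate all seven classifiers
#'
#' @inheritParams cross_validate
#' @param classifiers which classifiers to run; default all seven.
#' @return A tibble of [glance.dr_cv()] rows, one per classifier, with the
#'   `dr_cv` objects in a `cv` list-column.
#' @export
cross_validate_all <- function(features, labels,
                               classifiers = dr_classifier_names(),
                               rounds = 100, folds = 3, seed = 1,
                               ridge = 1e-4) {
  cvs <- lapply(classifiers, function(cl) {
    cross_validate(features, labels, cl, rounds = rounds, folds = folds,
                   seed = seed, ridge = ridge)
  })
  out <- dplyr::bind_rows(lapply(cvs, glance))
  out$cv <- cvs
  out
}

#' Filter repositioning candidates
#'
#' The candidate shortlist keeps FDA-approved compounds with percentile
#' rank strictly above `threshold`, ordered by rank descending. Compounds
#' flagged as not passing the blood-brain barrier are retained but marked
#' with `bbb_warning = TRUE` so that a reviewer can keep or drop them —
#' high-scoring non-permeant candidates can still be of interest.
#'
#' @param ranks tibble from [percentile_rank()].
#' @param catalog a [dr_catalog()] supplying `fda_approved` and `bbb`.
#' @param threshold percentile cut, strict. Default 0.9.
#' @return A tibble `compound_id`, `display_name`, `dr_score`,
#'   `percentile`, `bbb`, `bbb_warning`, ordered by rank descending.
#' @export
filter_candidates <- function(ranks, catalog, threshold = 0.9) {
  ranks |>
    dplyr::inner_join(catalog$compounds, by = "compound_id") |>
    dplyr::filter(.data$fda_approved, .data$percentile > threshold) |>
    dplyr::mutate(bbb_warning = .data$bbb == "no") |>
    dplyr::arrange(dplyr::desc(.data$percentile),
                   dplyr::desc(.data$dr_score), .data$compound_id) |>
    dplyr::select("compound_id", "display_name", "dr_score", "percentile",
                  "bbb", "bbb_warning")
}
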