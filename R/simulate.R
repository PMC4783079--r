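#' Parameters of a synthetic repositioning world
#'
#' The generator emulates the set-level structure of a real
#' signature-based repositioning study at desk scale: a few hundred
#' compounds with class-structured fingerprints (scaffold analogs),
#' target gene sets, multi-context expression signatures whose
#' disease-gene content is the tunable E-channel signal, a known-drug /
#' cancer-active labelling with hidden hits, noisy HTS assays and pathway
#' collections with planted mode-of-action structure. Signal channels are
#' independently switchable (`e_signal_fraction`, `t_signal_prob`) so
#' which-signature-carries-signal questions become controlled
#' experiments.
#'
#' @param n_compounds compounds in the world (400).
#' @param n_active truly active compounds (60).
#' @param n_kd known drugs, drawn from the actives (20).
#' @param n_cd_extra further actives labelled "active in other cancers"
#'   (20); `CD = KD + extras`, and actives outside CD are the hidden
#'   hits.
#' @param gene_universe_size expression gene universe (2000).
#' @param e_sig_size genes per direction in an E signature (100).
#' @param n_contexts cell contexts per compound (3).
#' @param disease_gene_pool disease-associated genes, split evenly into an
#'   up- and a down-pool (300).
#' @param e_signal_fraction fraction of an active compound's up/down genes
#'   drawn from the disease pools (0.5); 0 gives a null world.
#' @param t_pool_size target gene pool (50).
#' @param t_per_compound targets per compound (3).
#' @param t_signal_prob probability an active's target is drawn from the
#'   disease-linked half of the target pool (0 by default: no T signal).
#' @param fp_length fingerprint length (1024).
#' @param fp_on_bits on-bits per fingerprint (120).
#' @param n_scaffolds scaffold prototypes (25); same-scaffold compounds
#'   are high-Tanimoto analogs.
#' @param scaffold_flip_rate per-bit mutation rate off the scaffold
#'   prototype (0.05), on-bit count preserved.
#' @param context_noise fraction of E genes re-drawn per context (0.2).
#' @param n_pathways,pathway_size pathway collection shape (60 sets of
#'   40).
#' @param n_moa_groups,moa_drugs_per_group,moa_gene_fraction planted
#'   mode-of-action structure: for each group, one designated pathway is
#'   seeded into its member drugs' up or down gene draws at the given
#'   fraction (2 groups of 4 drugs, fraction 0.4).
#' @param n_assays HTS assays (3).
#' @param assay_coverage fraction of compounds tested per assay (0.7).
#' @param hts_noise hit-list contamination: each tested active is missed
#'   with this probability, and spurious hits numbering this fraction of
#'   the true hit list are added from tested inactives (0.05).
#' @param fda_fraction fraction of compounds flagged FDA-approved (0.5).
#' @param seed integer seed; all randomness flows from it through
#'   per-stage subseeds, so regeneration is stable.
#' @return A validated list of class `world_params`.
#' @export
world_params <- function(n_compounds = 400, n_active = 60, n_kd = 20,
                         n_cd_extra = 20, gene_universe_size = 2000,
                         e_sig_size = 100, n_contexts = 3,
                         disease_gene_pool = 300, e_signal_fraction = 0.5,
                         t_pool_size = 50, t_per_compound = 3,
                         t_signal_prob = 0, fp_length = 1024,
                         fp_on_bits = 120, n_scaffolds = 25,
                         scaffold_flip_rate = 0.05, context_noise = 0.2,
                         n_pathways = 60, pathway_size = 40,
                         n_moa_groups = 2, moa_drugs_per_group = 4,
                         moa_gene_fraction = 0.4, n_assays = 3,
                         assay_coverage = 0.7, hts_noise = 0.05,
                         fda_fraction = 0.5, seed = 1) {
  p <- as.list(environment())
  if (!(p$n_kd + p$n_cd_extra <= p$n_active && p$n_active <= p$n_compounds)) {
    abort("need n_kd + n_cd_extra <= n_active <= n_compounds")
  }
  if (2 * p$e_sig_size > p$gene_universe_size) {
    abort("gene universe too small for the E signature size")
  }
  if (p$disease_gene_pool + 2 * p$e_sig_size > p$gene_universe_size) {
    abort("gene universe too small for disease pool plus background draws")
  }
  probs <- c(p$e_signal_fraction, p$t_signal_prob, p$scaffold_flip_rate,
             p$context_noise, p$assay_coverage, p$hts_noise,
             p$fda_fraction, p$moa_gene_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (p$fp_on_bits >= p$fp_length) abort("fp_on_bits must be < fp_length")
  if (p$t_pool_size > p$gene_universe_size) abort("target pool too large")
  if (p$n_moa_groups * p$moa_drugs_per_group > p$n_active - p$n_kd) {
    abort("not enough non-KD actives for the requested MOA groups")
  }
  if (p$n_moa_groups > p$n_pathways) abort("not enough pathways for MOA groups")
  structure(p, class = "world_params")
}

# sample k items, deduplicated against `avoid`, refilled from `backup`
draw_from <- function(pool, k, avoid = character()) {
  pool <- setdiff(pool, avoid)
  if (length(pool) < k) abort("draw pool too small; relax world parameters")
  sample(pool, k)
}

#' Generate a synthetic repositioning world
#'
#' See [world_params()] for the statistical structure. Everything is
#' returned in memory — a ready [dr_catalog()] plus the ground truth — and
#' can be written to the package's standard file formats with
#' [write_world()], whose outputs round-trip through [load_catalog()].
#'
#' @param params a [world_params()] list.
#' @return A list of class `dr_world`: `catalog` (a [dr_catalog()]),
#'   `truth` (active/KD/CD/hidden-hit ids, per-assay hit lists, disease
#'   pools, planted MOA map, scaffold assignment), `params`.
#' @export
generate_world <- function(params = world_params()) {
  p <- params
  withr::with_seed(p$seed, {
    stage_seed <- sample.int(2147483646L, 8)
  })
  ids <- sprintf("cpd%04d", seq_len(p$n_compounds))
  genes <- sprintf("g%05d", seq_len(p$gene_universe_size))

  ## labels -----------------------------------------------------------
  lab <- withr::with_seed(stage_seed[1], {
    active <- sort(sample(ids, p$n_active))
    kd <- sort(sample(active, p$n_kd))
    cd_extra <- sort(sample(setdiff(active, kd), p$n_cd_extra))
    # MOA groups never overlap the known drugs: planted pathway genes in
    # the benchmark positives would couple the enrichment channel to the
    # classifier benchmark and de-null the rho_E = 0 world
    moa_pool <- sample(setdiff(active, kd))
    moa_groups <- lapply(seq_len(p$n_moa_groups), function(g) {
      moa_pool[seq_len(p$moa_drugs_per_group) +
                 (g - 1) * p$moa_drugs_per_group]
    })
    list(active = active, kd = kd, cd = sort(c(kd, cd_extra)),
         moa_groups = moa_groups)
  })

  ## pathways (drawn before expression so MOA genes can be planted) ----
  pw <- withr::with_seed(stage_seed[2], {
    pws <- lapply(seq_len(p$n_pathways), function(i) {
      sort(sample(genes, p$pathway_size))
    })
    names(pws) <- sprintf("pw%03d", seq_len(p$n_pathways))
    pws
  })
  moa_pathways <- names(pw)[seq_len(p$n_moa_groups)]
  moa_dirs <- rep(c("up", "down"), length.out = p$n_moa_groups)
  planted <- stats::setNames(
    rep(moa_pathways, each = p$moa_drugs_per_group),
    unlist(lab$moa_groups)
  )
  planted_dir <- stats::setNames(
    rep(moa_dirs, each = p$moa_drugs_per_group),
    unlist(lab$moa_groups)
  )

  ## fingerprints ------------------------------------------------------
  fp <- withr::with_seed(stage_seed[3], {
    scaffold_of <- sample(seq_len(p$n_scaffolds), p$n_compounds,
                          replace = TRUE)
    protos <- lapply(seq_len(p$n_scaffolds), function(i) {
      sort(sample(0:(p$fp_length - 1), p$fp_on_bits))
    })
    bits <- lapply(seq_len(p$n_compounds), function(i) {
      proto <- protos[[scaffold_of[i]]]
      drop <- proto[stats::runif(length(proto)) < p$scaffold_flip_rate]
      gained <- if (length(drop) > 0) {
        sample(setdiff(0:(p$fp_length - 1), proto), length(drop))
      } else integer()
      sort(c(setdiff(proto, drop), gained))
    })
    list(scaffold_of = stats::setNames(scaffold_of, ids), bits = bits)
  })

  ## targets -----------------------------------------------------------
  tg <- withr::with_seed(stage_seed[4], {
    t_pool <- sample(genes, p$t_pool_size)
    dis_t <- t_pool[seq_len(ceiling(p$t_pool_size / 2))]
    sets <- lapply(ids, function(id) {
      if (id %in% lab$active && p$t_signal_prob > 0) {
        from_dis <- stats::runif(p$t_per_compound) < p$t_signal_prob
        out <- character(p$t_per_compound)
        n_d <- sum(from_dis)
        if (n_d > 0) out[from_dis] <- sample(dis_t, n_d)
        if (n_d < p$t_per_compound) {
          out[!from_dis] <- draw_from(t_pool, p$t_per_compound - n_d,
                                      avoid = out[from_dis])
        }
        sort(unique(out))
      } else {
        sort(sample(t_pool, p$t_per_compound))
      }
    })
    list(sets = sets, dis_t = dis_t)
  })

  ## expression --------------------------------------------------------
  # Each compound owns an RNG substream and always draws fixed-length
  # disease-gene and background-gene sequences; the signal fraction only
  # decides how much of each sequence enters the signature. Worlds that
  # differ only in e_signal_fraction are therefore coupled (common random
  # numbers), and regenerating one compound never perturbs another.
  half <- floor(p$disease_gene_pool / 2)
  expr <- withr::with_seed(stage_seed[5], {
    dis_pool <- sample(genes, p$disease_gene_pool)
    dis_up <- dis_pool[seq_len(half)]
    dis_down <- dis_pool[(half + 1):p$disease_gene_pool]
    background <- setdiff(genes, dis_pool)
    k_sig <- round(p$e_signal_fraction * p$e_sig_size)
    k_moa <- round(p$moa_gene_fraction * p$e_sig_size)
    k_noise <- round(p$context_noise * p$e_sig_size)
    res_len <- p$e_sig_size + p$n_contexts * k_noise

    dis_sigs <- lapply(1:2, function(ds) {
      list(up = sort(sample(dis_up, min(p$e_sig_size, length(dis_up)))),
           down = sort(sample(dis_down, min(p$e_sig_size,
                                            length(dis_down)))))
    })
    cpd_seed <- sample.int(2147483646L, p$n_compounds)

    rows <- vector("list", p$n_compounds)
    for (i in seq_along(ids)) {
      id <- ids[i]
      rows[[i]] <- withr::with_seed(cpd_seed[i], {
        planted_part <- list(up = character(), down = character())
        if (id %in% names(planted)) {
          d <- planted_dir[[id]]
          # plant only the pathway's non-disease genes: keeps the
          # enrichment channel orthogonal to disease similarity
          avail <- setdiff(pw[[planted[[id]]]], dis_pool)
          planted_part[[d]] <- sample(avail, min(k_moa, length(avail)))
        }
        dis_seq <- list(
          up = sample(dis_up, min(p$e_sig_size, length(dis_up))),
          down = sample(dis_down, min(p$e_sig_size, length(dis_down)))
        )
        bgpool <- setdiff(background, unlist(planted_part))
        if (2 * res_len > length(bgpool)) {
          abort("draw pool too small; relax world parameters")
        }
        bg_seq <- sample(bgpool, 2 * res_len)
        bg <- list(up = bg_seq[seq_len(res_len)],
                   down = bg_seq[res_len + seq_len(res_len)])
        k_s <- if (id %in% lab$active) k_sig else 0
        out <- vector("list", p$n_contexts)
        for (dir in c("up", "down")) {
          n_pl <- length(planted_part[[dir]])
          n_dis <- min(k_s, p$e_sig_size - n_pl)
          n_bg <- p$e_sig_size - n_pl - n_dis
          base <- c(planted_part[[dir]],
                    dis_seq[[dir]][seq_len(n_dis)],
                    bg[[dir]][seq_len(n_bg)])
          for (cx in seq_len(p$n_contexts)) {
            ctx_set <- base
            if (k_noise > 0) {
              idx <- sample(p$e_sig_size, k_noise)
              # noise slices anchored at the sequence end, so they are
              # identical across signal fractions
              ctx_set[idx] <- bg[[dir]][p$e_sig_size +
                                          (cx - 1) * k_noise +
                                          seq_len(k_noise)]
            }
            out[[cx]][[dir]] <- sort(ctx_set)
          }
        }
        dplyr::bind_rows(lapply(seq_len(p$n_contexts), function(cx) {
          tibble::tibble(owner_id = id, context = sprintf("ctx%d", cx),
                         up = list(out[[cx]]$up),
                         down = list(out[[cx]]$down))
        }))
      })
    }
    list(rows = dplyr::bind_rows(rows), dis_up = dis_up,
         dis_down = dis_down, dis_sigs = dis_sigs)
  })

  ## HTS assays --------------------------------------------------------
  assays <- withr::with_seed(stage_seed[6], {
    dplyr::bind_rows(lapply(seq_len(p$n_assays), function(a) {
      tested <- sort(sample(ids, round(p$assay_coverage * p$n_compounds)))
      true_hits <- intersect(tested, lab$active)
      missed <- true_hits[stats::runif(length(true_hits)) < p$hts_noise]
      n_fp <- round(p$hts_noise * length(true_hits))
      spurious <- if (n_fp > 0) {
        sample(setdiff(tested, lab$active), n_fp)
      } else character()
      hits <- sort(c(setdiff(true_hits, missed), spurious))
      tibble::tibble(assay_id = sprintf("assay%d", a),
                     compound_id = tested, hit = tested %in% hits)
    }))
  })

  ## annotations -------------------------------------------------------
  ann <- withr::with_seed(stage_seed[7], {
    tibble::tibble(
      compound_id = ids,
      display_name = paste0("compound-", seq_along(ids)),
      fda_approved = stats::runif(p$n_compounds) < p$fda_fraction,
      bbb = sample(c("yes", "no", "unknown"), p$n_compounds,
                   replace = TRUE, prob = c(0.5, 0.2, 0.3))
    )
  })

  ## assemble ----------------------------------------------------------
  s_sigs <- signature_tbl(ids, "compound", "S",
                          features = lapply(fp$bits, as.character))
  t_sigs <- signature_tbl(ids, "compound", "T", features = tg$sets)
  e_up <- signature_tbl(expr$rows$owner_id, "compound", "E", "up",
                        context = expr$rows$context,
                        features = expr$rows$up)
  e_dn <- signature_tbl(expr$rows$owner_id, "compound", "E", "down",
                        context = expr$rows$context,
                        features = expr$rows$down)
  dis_sig_tbl <- dplyr::bind_rows(lapply(seq_along(expr$dis_sigs),
                                         function(i) {
    signature_tbl(rep("disease1", 2), "disease", "E", c("up", "down"),
                  context = sprintf("dataset%d", i),
                  features = list(expr$dis_sigs[[i]]$up,
                                  expr$dis_sigs[[i]]$down))
  }))
  catalog <- dr_catalog(
    compounds = ann,
    signatures = dplyr::bind_rows(s_sigs, t_sigs, e_up, e_dn),
    disease = disease_reference("disease1", kd_ids = lab$kd,
                                cd_ids = lab$cd,
                                signatures = dis_sig_tbl),
    pathways = pathway_collection(pw, universe = genes),
    assays = assays,
    fp_length = p$fp_length
  )
  truth <- list(
    active_ids = lab$active, kd_ids = lab$kd, cd_ids = lab$cd,
    hidden_hit_ids = sort(setdiff(lab$active, lab$cd)),
    hts_hit_ids = split(assays$compound_id[assays$hit],
                        assays$assay_id[assays$hit]),
    disease_pool_up = sort(expr$dis_up),
    disease_pool_down = sort(expr$dis_down),
    planted_pathway_map = lapply(stats::setNames(nm = names(planted)),
                                 function(id) {
      list(pathway = unname(planted[[id]]),
           direction = unname(planted_dir[[id]]))
    }),
    scaffold_of = as.list(fp$scaffold_of)
  )
  structure(list(catalog = catalog, truth = truth, params = p),
            class = "dr_world")
}

#' @export
print.dr_world <- function(x, ...) {
  cat("<dr_world> seed ", x$params$seed, ", e_signal_fraction ",
      x$params$e_signal_fraction, "\n", sep = "")
  print(x$catalog)
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Emits the full catalog file set in the package's standard text formats
#' (fingerprint TSV, target/expression/disease/pathway GMT, annotation and
#' assay TSVs, id lists), a `config.yaml` that [load_catalog()] accepts,
#' plus `truth.json` and `params_echo.json`.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory, created if needed.
#' @return The config path, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cat <- world$catalog
  sig <- cat$signatures
  fp <- sig[sig$sig_type == "S", ]
  write_fingerprints(
    tibble::tibble(compound_id = fp$owner_id,
                   bits = lapply(fp$features, as.integer)),
    file.path(dir, "fingerprints.tsv")
  )
  tg <- sig[sig$sig_type == "T", ]
  write_gmt(tibble::tibble(set_id = tg$owner_id, description = "targets",
                           genes = tg$features),
            file.path(dir, "targets.gmt"))
  write_gmt(format_expression_gmt(sig), file.path(dir, "expression.gmt"))
  write_gmt(format_expression_gmt(cat$disease$signatures),
            file.path(dir, "disease_expression.gmt"))
  readr::write_tsv(
    tibble::tibble(compound_id = cat$compounds$compound_id,
                   name = cat$compounds$display_name,
                   fda_approved = as.integer(cat$compounds$fda_approved),
                   bbb = cat$compounds$bbb),
    file.path(dir, "annotations.tsv")
  )
  writeLines(cat$disease$kd_ids, file.path(dir, "kd.txt"))
  writeLines(cat$disease$cd_ids, file.path(dir, "cd.txt"))
  write_gmt(tibble::tibble(set_id = names(cat$pathways$pathways),
                           description = "pathway",
                           genes = cat$pathways$pathways),
            file.path(dir, "pathways.gmt"))
  writeLines(cat$pathways$universe, file.path(dir, "universe.txt"))
  writeLines(character(), file.path(dir, "pathway_exclude.txt"))
  readr::write_tsv(
    dplyr::mutate(cat$assays, hit = as.integer(.data$hit)),
    file.path(dir, "assays.tsv")
  )
  config <- list(
    fp_length = cat$fp_length,
    fingerprints = "fingerprints.tsv",
    targets_gmt = "targets.gmt",
    expression_gmt = "expression.gmt",
    annotations = "annotations.tsv",
    disease = list(id = cat$disease$disease_id, kd = "kd.txt",
                   cd = "cd.txt",
                   signatures_gmt = "disease_expression.gmt"),
    pathways = list(gmt = "pathways.gmt", exclude = "pathway_exclude.txt",
                    universe = "universe.txt"),
    assays = "assays.tsv"
  )
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(unclass(world$params),
                       file.path(dir, "params_echo.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "config.yaml"))
}
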