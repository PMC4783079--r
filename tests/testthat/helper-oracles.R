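# Independent brute-force oracles: naive double loops and enumeration,
# sharing no code with the package implementations they check.

bf_tanimoto <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  n_int <- 0
  for (x in a) if (any(x == b)) n_int <- n_int + 1
  n_uni <- length(b)
  for (x in a) if (!any(x == b)) n_uni <- n_uni + 1
  n_int / n_uni
}

bf_mean_pairwise <- function(sets_a, sets_b) {
  if (length(sets_a) == 0 || length(sets_b) == 0) return(NA_real_)
  vals <- c()
  for (a in sets_a) for (b in sets_b) vals <- c(vals, bf_tanimoto(a, b))
  mean(vals)
}

# Association features re-derived with explicit loops over raw catalog
# pieces (combined E sets = union of up/down per owner+context).
bf_features <- function(catalog, loo_kd = FALSE) {
  sigs <- catalog$signatures
  combined_e_sets <- function(owner) {
    e <- sigs[sigs$owner_id == owner & sigs$sig_type == "E", ]
    out <- list()
    for (cx in unique(e$context)) {
      out[[length(out) + 1]] <- unique(unlist(e$features[e$context == cx]))
    }
    out
  }
  sets_of <- function(owner, type) {
    if (type == "E") return(combined_e_sets(owner))
    sigs$features[sigs$owner_id == owner & sigs$sig_type == type]
  }
  kd <- catalog$disease$kd_ids
  pool_of <- function(type, without = NULL) {
    out <- list()
    for (d in setdiff(kd, without)) out <- c(out, sets_of(d, type))
    out
  }
  dis <- catalog$disease$signatures
  dis_pool <- list()
  for (cx in unique(dis$context)) {
    dis_pool[[length(dis_pool) + 1]] <-
      unique(unlist(dis$features[dis$context == cx]))
  }
  ids <- catalog$compounds$compound_id
  res <- data.frame(compound_id = ids)
  spec <- list(S_S = c("S", "S"), T_T = c("T", "T"), T_Ekd = c("T", "E"),
               T_Edis = c("T", "dis"), E_T = c("E", "T"),
               E_Ekd = c("E", "E"), E_Edis = c("E", "dis"))
  for (f in names(spec)) {
    vals <- numeric(0)
    for (id in ids) {
      cs <- sets_of(id, spec[[f]][1])
      without <- if (loo_kd && id %in% kd) id
      pool <- if (spec[[f]][2] == "dis") dis_pool else
        pool_of(spec[[f]][2], without = without)
      vals <- c(vals, bf_mean_pairwise(cs, pool))
    }
    res[[f]] <- vals
  }
  res
}

bf_auc <- function(scores, positives, negatives) {
  sp <- scores[names(scores) %in% positives]
  sn <- scores[names(scores) %in% negatives]
  tot <- 0
  for (p in sp) for (n in sn) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# Exhaustive enumeration of all C(N, n) draws; successes are 1..K.
bf_hypergeom_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  draws <- utils::combn(N, n)
  hits <- 0
  for (j in seq_len(ncol(draws))) {
    if (sum(draws[, j] <= K) >= k) hits <- hits + 1
  }
  hits / ncol(draws)
}

bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- 1
  for (pos in m:1) {
    i <- ord[pos]
    running <- min(running, p[i] * m / pos)
    q[i] <- running
  }
  q
}

bf_harmonic_mean <- function(p) {
  s <- 0
  for (x in p) s <- s + 1 / x
  length(p) / s
}

bf_partition <- function(hits, tested, kd, cd, fp_sets, threshold = 0.7,
                         min_analogs = 2, scope = NULL) {
  if (!is.null(scope)) {
    tested <- intersect(tested, scope)
    hits <- intersect(hits, tested)
  }
  out <- list(excluded_known = character(), anticancer = character(),
              novel = character(), nonhits = setdiff(tested, hits))
  for (h in hits) {
    if (h %in% kd) {
      out$excluded_known <- c(out$excluded_known, h)
    } else if (h %in% cd) {
      out$anticancer <- c(out$anticancer, h)
    } else {
      n_analog <- 0
      for (d in cd) {
        best <- 0
        for (a in fp_sets[[h]]) for (b in fp_sets[[d]]) {
          best <- max(best, bf_tanimoto(a, b))
        }
        if (best > threshold) n_analog <- n_analog + 1
      }
      if (n_analog >= min_analogs) {
        out$anticancer <- c(out$anticancer, h)
      } else {
        out$novel <- c(out$novel, h)
      }
    }
  }
  lapply(out, sort)
}

random_set <- function(universe, max_size = 30) {
  sample(universe, sample.int(max_size, 1))
}
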