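test_that("hypergeometric p matches closed cases and enumeration", {
  universe <- paste0("g", 1:10)
  # no overlap: upper tail at zero is exactly 1
  expect_identical(hypergeom_p(paste0("g", 1:3), paste0("g", 8:10)[0],
                               universe), 1)
  # all 5 draws inside the 5-gene pathway: 1 / C(10,5)
  expect_equal(hypergeom_p(paste0("g", 1:5), paste0("g", 1:5), universe),
               1 / 252, tolerance = 1e-12)
  # signature = universe makes the overlap certain
  expect_equal(hypergeom_p(universe, paste0("g", 1:4), universe), 1)
  expect_error(hypergeom_p("g1", "g2", character()), "empty")

  withr::local_seed(51)
  for (i in 1:25) {
    N <- sample(6:12, 1)
    uni <- paste0("u", 1:N)
    pw <- sample(uni, sample.int(N - 1, 1))
    sig <- sample(uni, sample.int(N - 1, 1))
    k <- length(intersect(sig, pw))
    want <- bf_hypergeom_upper(k, length(pw), length(sig), N)
    expect_equal(hypergeom_p(sig, pw, uni), want, tolerance = 1e-12)
  }
})

test_that("harmonic mean p-value behaves as the formula dictates", {
  expect_equal(harmonic_mean_p(c(0.2, 0.2, 0.2)), 0.2)
  expect_equal(harmonic_mean_p(c(0.01, 0.0001)), 2 / 10100,
               tolerance = 1e-15)
  expect_equal(harmonic_mean_p(0.42), 0.42)
  expect_error(harmonic_mean_p(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(harmonic_mean_p(numeric()), "empty")
  withr::local_seed(52)
  for (i in 1:20) {
    p <- runif(sample.int(8, 1), min = 1e-6)
    expect_lte(harmonic_mean_p(p), mean(p))
    expect_equal(harmonic_mean_p(p), bf_harmonic_mean(p),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment is step-up, monotone and permutation-consistent", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::local_seed(53)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bf_bh(p), tolerance = 1e-12)
    # step-up never adjusts below the raw p, and is exactly p at the max
    expect_true(all(q >= p - 1e-12))
    expect_equal(q[which.max(p)], max(p))
    # monotone: larger p never gets a smaller q
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-15)
  }
})

test_that("the worked-example enrichment profile matches the stored oracle", {
  cat <- generate_worked_example()
  prof <- enrich_drug(cat, "c1", q_cutoff = 0.1)
  want <- worked_example_table("enrichment_c1.tsv")
  got <- prof[match(paste(want$pathway_id, want$direction),
                    paste(prof$pathway_id, prof$direction)), ]
  expect_equal(got$p_rep, want$p_rep, tolerance = 1e-12)
  expect_equal(got$q, want$q, tolerance = 1e-12)
  expect_equal(got$overlap, want$overlap)
  expect_equal(got$significant, want$significant)
  # the planted pathway-direction row carries the profile's smallest p
  expect_equal(got$pathway_id[which.min(got$p_rep)], "pwA")
  expect_equal(got$direction[which.min(got$p_rep)], "up")
})

test_that("single-context drugs reduce to one hypergeometric p", {
  cat <- generate_worked_example()
  prof <- enrich_drug(cat, "c3")
  sigs <- cat$signatures
  up <- sigs$features[[which(sigs$owner_id == "c3" &
                               sigs$direction == "up")]]
  direct <- hypergeom_p(up, cat$pathways$pathways$pwC,
                        cat$pathways$universe)
  expect_equal(prof$p_rep[prof$pathway_id == "pwC" &
                            prof$direction == "up"], direct)
  # q_cutoff = 0 flags nothing
  prof0 <- enrich_drug(cat, "c3", q_cutoff = 0)
  expect_false(any(prof0$significant))
  expect_error(enrich_drug(cat, "nosuch"), "no E signatures")
})

test_that("cosine distance matches hand geometry", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 2)), 1)
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero vector")
})

test_that("clustering separates planted profile groups and merges twins", {
  # two groups with disjoint significant pathway supports
  mk_prof <- function(drug, pw_on) {
    tibble::tibble(
      drug_id = drug,
      pathway_id = rep(paste0("pw", 1:4), each = 2),
      direction = rep(c("up", "down"), 4),
      p_rep = ifelse(rep(paste0("pw", 1:4), each = 2) %in% pw_on,
                     1e-6, 1),
      q = ifelse(rep(paste0("pw", 1:4), each = 2) %in% pw_on, 1e-5, 1),
      overlap = 1L, significant = NA
    ) |>
      dplyr::mutate(significant = .data$q < 0.05)
  }
  profs <- dplyr::bind_rows(
    mk_prof("a1", c("pw1", "pw2")), mk_prof("a2", c("pw1", "pw2")),
    mk_prof("b1", c("pw3", "pw4")), mk_prof("b2", c("pw3", "pw4"))
  )
  cl <- cluster_profiles(profs, k = 2)
  expect_equal(cl$clusters[["a1"]], cl$clusters[["a2"]])
  expect_equal(cl$clusters[["b1"]], cl$clusters[["b2"]])
  expect_false(cl$clusters[["a1"]] == cl$clusters[["b1"]])
  expect_equal(cl$distances[["a1", "b1"]], 1, tolerance = 1e-9)

  # a duplicated profile sits at distance zero and merges first
  profs2 <- dplyr::bind_rows(profs,
                             dplyr::mutate(mk_prof("a3", c("pw1", "pw2")),
                                           drug_id = "a1twin"))
  cl2 <- cluster_profiles(profs2, k = 2)
  expect_equal(cl2$distances[["a1", "a1twin"]], 0)
  expect_equal(cl2$hclust$height[1], 0)
  expect_equal(cl2$clusters[["a1"]], cl2$clusters[["a1twin"]])

  # identical single-pathway profiles: all distances zero
  same <- dplyr::bind_rows(mk_prof("x", "pw1"), mk_prof("y", "pw1"),
                           mk_prof("z", "pw1"))
  cl3 <- cluster_profiles(same, k = 1)
  expect_true(all(abs(cl3$distances) < 1e-12))
  expect_error(cluster_profiles(profs[profs$drug_id == "a1", ]),
               "at least two")
  expect_error(cluster_profiles(dplyr::mutate(profs, q = 1), k = 2),
               "loosen")
})

test_that("pathway collections intersect with the universe and exclude ids", {
  expect_warning(
    pc <- pathway_collection(list(a = c("g1", "g2"), b = "zz"),
                             universe = c("g1", "g2", "g3")),
    "dropping 1"
  )
  expect_equal(names(pc$pathways), "a")
  pc2 <- pathway_collection(list(a = "g1", b = "g2"),
                            universe = c("g1", "g2"),
                            excluded_ids = "b")
  expect_equal(names(pc2$pathways), "a")
})
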