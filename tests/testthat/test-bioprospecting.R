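make_records <- function(ids, species, seqs, ...) {
  tibble::tibble(id = ids, species = species, sequence = seqs,
                 length = nchar(seqs), ...)
}

test_that("FASTA round trip preserves records; empty files give empty tables", {
  fam <- generate_sequence_families(
    family_spec(2, 3, seed_length_mean = 40, seed_length_sd = 3,
                rng_seed = 5))
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fam$records, tf)
  back <- read_fasta(tf)
  expect_identical(as.data.frame(back), as.data.frame(fam$records))

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fasta(empty)), 0L)
})

test_that("dedupe keeps the longest sequence per species, ties by id", {
  rec <- make_records(
    ids = c("b2", "a1", "c3", "z9"),
    species = c("Sp_one", "Sp_one", "Sp_one", "Sp_two"),
    seqs = c(strrep("A", 450), strrep("C", 450), strrep("D", 400),
             strrep("E", 100)))
  out <- dedupe_by_species(rec)
  expect_setequal(out$id, c("a1", "z9"))
  # all-distinct input is untouched
  rec2 <- make_records(c("x", "y"), c("S1", "S2"), c("AAA", "CCC"))
  expect_identical(dedupe_by_species(rec2), rec2)
  rec3 <- make_records("x", NA_character_, "AAA")
  expect_error(dedupe_by_species(rec3), "without species")
})

test_that("complete-linkage clustering matches hand-executed agglomeration", {
  d <- as.dist(manual_agglomeration$d)
  hc <- hierarchical_cluster(d)
  expect_equal(hc$height, manual_agglomeration$heights)
  expect_equal(cut_tree(hc, k = 2)[names(manual_agglomeration$k2)],
               manual_agglomeration$k2)
  # two items: single merge at their distance
  d2 <- as.dist(matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("x", "y"))))
  expect_equal(hierarchical_cluster(d2)$height, 0.3)
  # zero distances: all merges at height 0
  d0 <- as.dist(matrix(0, 5, 5))
  expect_true(all(hierarchical_cluster(d0)$height == 0))
  expect_error(hierarchical_cluster(as.dist(matrix(NA_real_, 2, 2))), "NA")
})

test_that("cut_tree handles degenerate k and agrees between k and height cuts", {
  d <- as.dist(manual_agglomeration$d)
  hc <- hierarchical_cluster(d)
  n <- 4
  expect_equal(as.integer(cut_tree(hc, k = n)), 1:4)   # all singletons
  expect_equal(unique(as.integer(cut_tree(hc, k = 1))), 1L)
  expect_error(cut_tree(hc, k = 9), "'k' must be in")
  # a height between the (n-k)th and (n-k+1)th merge heights gives k clusters
  for (k in 2:3) {
    h <- mean(manual_agglomeration$heights[(n - k):(n - k + 1)])
    expect_equal(cut_tree(hc, k = k), cut_tree(hc, h = h))
  }
})

test_that("clustering recovers planted families exactly (ARI 1)", {
  fam <- generate_sequence_families(
    family_spec(3, 6, seed_length_mean = 70, seed_length_sd = 6,
                within_family_identity = 0.85,
                between_family_identity_max = 0.5, rng_seed = 21))
  m <- identity_matrix(fam$records)
  cl <- cut_tree(hierarchical_cluster(m), k = 3)
  expect_equal(ari(cl, fam$labels), 1)
  # invariant under input permutation, up to label renaming
  perm <- sample(nrow(fam$records))
  m2 <- identity_matrix(fam$records[perm, ])
  cl2 <- cut_tree(hierarchical_cluster(m2), k = 3)
  expect_equal(ari(cl2[fam$records$id], cl[fam$records$id]), 1)
})

test_that("filters discard by first violated rule with stated reasons", {
  rec <- make_records(
    ids = c("short", "ok", "pathogen"),
    species = paste0("S", 1:3),
    seqs = c(strrep("A", 209), strrep("L", 460), strrep("K", 470)),
    pathogenic_host = c(FALSE, FALSE, TRUE))
  out <- filter_candidates(rec, list(min_length = 300,
                                     exclude_flags = "pathogenic_host"))
  expect_setequal(out$kept$id, "ok")
  expect_equal(out$discarded$reason[out$discarded$id == "short"], "length")
  expect_equal(out$discarded$reason[out$discarded$id == "pathogen"],
               "pathogenic_host")
  # empty rule set keeps everything
  out2 <- filter_candidates(rec, list())
  expect_identical(out2$kept, rec)
  # mass window: poly-L at 460 aa is ~52 kDa
  out3 <- filter_candidates(rec, list(mass_kda_range = c(45, 55)))
  expect_true("ok" %in% out3$kept$id)
  expect_equal(unique(out3$discarded$reason), "mass")
})

test_that("theoretical mass matches residue-sum arithmetic", {
  # 3x glycine: 3 * 57.0519 + 18.0153 Da
  expect_equal(theoretical_mass_kda("GGG"), (3 * 57.0519 + 18.0153) / 1000)
  expect_error(theoretical_mass_kda("GGZ"), "illegal residue")
})

test_that("representative selection is one per cluster, greedy on diversity", {
  fam <- generate_sequence_families(
    family_spec(3, 4, seed_length_mean = 60, seed_length_sd = 0,
                rng_seed = 13))
  m <- identity_matrix(fam$records)
  cl <- cut_tree(hierarchical_cluster(m), k = 3)
  sel <- select_representatives(fam$records, cl, m)
  expect_equal(nrow(sel$selected), 3L)
  expect_equal(unname(cl[sel$selected$id]), sel$selected$cluster)
  expect_length(sel$empty_clusters, 0L)
  # a cluster whose members all fail the filter is reported empty
  rules <- list(exclude_flags = "pathogenic_host")
  rec2 <- fam$records
  rec2$pathogenic_host[cl[rec2$id] == 2] <- TRUE
  sel2 <- select_representatives(rec2, cl, m, rules)
  expect_equal(sel2$empty_clusters, 2L)
  expect_equal(nrow(sel2$selected), 2L)
  # single admissible record in a single cluster is chosen
  one <- fam$records[1, ]
  m1 <- identity_matrix(rbind(one, fam$records[2, ]))
  cl1 <- setNames(c(1L, 1L), c(one$id, fam$records$id[2]))
  sel3 <- select_representatives(fam$records[1:2, ], cl1, m1)
  expect_equal(nrow(sel3$selected), 1L)
})

test_that("summary statistics use sample sd and cover the stated range", {
  one <- make_records("a", "S", strrep("A", 471))
  sm <- cluster_summary(one)
  expect_equal(sm$mean_length, 471)
  expect_equal(sm$sd_length, 0)
  two <- make_records(c("a", "b"), c("S1", "S2"),
                      c(strrep("A", 209), strrep("A", 568)))
  sm2 <- cluster_summary(two)
  expect_equal(sm2$min_length, 209)
  expect_equal(sm2$max_length, 568)
  expect_equal(sm2$sd_length, sd(c(209, 568)))
})
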