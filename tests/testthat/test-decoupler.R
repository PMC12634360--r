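test_that("token edit distance matches independent oracles", {
  expect_identical(seq_levenshtein(c("A", "B", "C"), c("A", "B", "C")), 0L)
  expect_identical(seq_levenshtein(character(0), c("A", "B")), 2L)
  ex <- seq_levenshtein(c("A", "B", "C", "D"), c("B", "C", "D", "E"))
  expect_identical(ex, lev_rec(c("A", "B", "C", "D"),
                               c("B", "C", "D", "E")))
  expect_identical(ex, 2L)

  # whole-token semantics: multi-character names are single edit units
  expect_identical(seq_levenshtein(c("Angle", "IAN"), c("Angle")), 1L)

  # exhaustive recursion oracle on all pairs of length <= 2, DP oracle on
  # random longer pairs
  short <- all_seqs(c("x", "y", "z"), 2)
  for (a in short) for (b in short) {
    expect_identical(seq_levenshtein(a, b), lev_rec(a, b))
  }
  set.seed(10)
  for (i in 1:200) {
    a <- sample(c("x", "y", "z"), sample(0:6, 1), replace = TRUE)
    b <- sample(c("x", "y", "z"), sample(0:6, 1), replace = TRUE)
    expect_identical(seq_levenshtein(a, b), lev_dp(a, b))
  }
})

test_that("edit distance satisfies the metric axioms", {
  set.seed(11)
  rand_seq <- function() sample(LETTERS[1:4], sample(0:5, 1), replace = TRUE)
  for (i in 1:100) {
    a <- rand_seq(); b <- rand_seq(); c_ <- rand_seq()
    dab <- seq_levenshtein(a, b)
    expect_identical(dab, seq_levenshtein(b, a))
    expect_identical(dab == 0L, identical(a, b))
    expect_lte(seq_levenshtein(a, c_), dab + seq_levenshtein(b, c_))
  }
})

test_that("the distance matrix is consistent with elementwise calls", {
  seqs <- list(s1 = c("A", "B"), s2 = c("A", "B"), s3 = c("C"))
  D <- pairwise_distances(seqs)
  expect_identical(D["s1", "s2"], 0)
  expect_identical(D["s1", "s3"], as.numeric(seq_levenshtein(seqs$s1,
                                                             seqs$s3)))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_error(pairwise_distances(list(a = "A")), "at least 2")
  expect_error(pairwise_distances(stats::setNames(seqs, c("a", "a", "b"))),
               "unique")
})

test_that("average-linkage clustering recovers block structure", {
  ids <- c("s1", "s2", "s3", "s4")
  D <- matrix(10, 4, 4, dimnames = list(ids, ids))
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 1
  diag(D) <- 0
  part <- cluster_surgeons(D, k = 2)
  expect_identical(part$cluster[1], part$cluster[2])
  expect_identical(part$cluster[3], part$cluster[4])
  expect_false(part$cluster[1] == part$cluster[3])

  # brute force over all 2-partitions: minimal total within-cluster average
  # distance is the block split
  best <- NULL; best_val <- Inf
  for (mask in 1:7) { # non-trivial bipartitions of 4 items
    g <- as.logical(bitwAnd(mask, 2^(0:3)) > 0)
    if (all(g) || !any(g)) next
    within <- function(idx) {
      if (sum(idx) < 2) return(0)
      mean(D[idx, idx][upper.tri(D[idx, idx])])
    }
    val <- within(g) + within(!g)
    if (val < best_val) { best_val <- val; best <- g }
  }
  expect_identical(sort(ids[best]), c("s1", "s2"))

  # two surgeons: one cluster each
  part2 <- cluster_surgeons(D[1:2, 1:2], k = 2)
  expect_identical(sort(part2$cluster), c(1L, 2L))
  expect_error(cluster_surgeons(D, k = 5), "exceeds")
})

test_that("tied distances resolve deterministically and order-invariantly", {
  ids <- c("s1", "s2", "s3")
  D <- matrix(2, 3, 3, dimnames = list(ids, ids))
  diag(D) <- 0
  p1 <- cluster_surgeons(D, k = 2)
  p2 <- cluster_surgeons(D, k = 2)
  expect_identical(p1$cluster, p2$cluster)

  # permuting the input order changes nothing up to relabeling
  cfg <- small_clinic_cfg(17)
  ds <- generate_dataset(cfg)
  seqs <- preference_sequences(ds)
  Dm <- pairwise_distances(seqs)
  perm <- c(3, 1, 4, 2)
  pa <- cluster_surgeons(Dm, k = 2)
  pb <- cluster_surgeons(Dm[perm, perm], k = 2)
  expect_equal(partition_ari(pa, pb), 1)
})

test_that("new surgeons are assigned to the nearest experience group", {
  seqs <- tibble::tibble(
    surgeon_id = c("s1", "s2", "s3", "s4"),
    tokens = list(c("A", "B", "C"), c("A", "B", "D"),
                  c("X", "Y", "Z"), c("X", "Y", "W"))
  )
  part <- cluster_surgeons(pairwise_distances(seqs), k = 2)
  cl_abc <- part$cluster[part$surgeon_id == "s1"]
  expect_identical(assign_surgeon(c("A", "B", "C"), part, seqs), cl_abc)
  cl_xyz <- part$cluster[part$surgeon_id == "s3"]
  expect_identical(assign_surgeon(c("X", "Y", "Q"), part, seqs), cl_xyz)
  # a novel token is equidistant from both groups: lower cluster id wins
  expect_identical(assign_surgeon("Q", part, seqs), 1L)
})

test_that("sample routing uses surgeon lookup first, then centroids", {
  cfg <- small_clinic_cfg(19)
  ds <- generate_dataset(cfg)
  part <- decouple_surgeons(ds)
  cl <- assign_samples(ds[ds$surgeon_id == "s9", ][1:3, ], part, ds)
  expect_identical(cl, rep(part$cluster[part$surgeon_id == "s9"], 3))

  # unknown surgeon whose record sits exactly on the cluster-1 centroid
  sch <- ddss_schema()
  rec <- ds[1, ]
  rec$surgeon_id <- "stranger"
  rec$record_id <- "stranger-1"
  train_cl <- dplyr::inner_join(ds, part, by = "surgeon_id")
  cent_codes <- colMeans(ddss:::record_matrix(
    train_cl[train_cl$cluster == 1, ], sch))
  for (ab in names(cent_codes)) rec[[ab]] <- cent_codes[[ab]]
  expect_identical(assign_samples(rec, part, ds), 1L)

  # centroid mode ignores surgeon identity entirely
  cl_cent <- assign_samples(ds[1:20, ], part, ds, method = "centroid")
  expect_true(all(cl_cent %in% c(1L, 2L)))
})

test_that("a held-out novice surgeon is assigned to the novice cluster", {
  hits <- vapply(1:50, function(s) {
    cfg <- default_config(seed = s)
    ds <- generate_dataset(cfg)
    train <- ds[ds$surgeon_id != "s8", , drop = FALSE]
    part <- decouple_surgeons(train)
    planted <- planted_partition(cfg)
    # the recovered cluster holding the majority of planted novices
    novice_cl <- part |>
      dplyr::inner_join(planted, by = "surgeon_id",
                        suffix = c("", "_true")) |>
      dplyr::filter(.data$cluster_true == 2L) |>
      dplyr::count(.data$cluster, sort = TRUE) |>
      dplyr::pull(.data$cluster) |>
      dplyr::first()
    held_out <- activation_sequence(
      fit_lasso_path(ds[ds$surgeon_id == "s8", , drop = FALSE]))
    assign_surgeon(held_out, part) == novice_cl
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("centroid routing sends feature-shifted records to their cluster", {
  # clusters must differ in feature space for centroid routing to carry
  # signal; plant a resistance/depth shift in cluster 2's records
  set.seed(33)
  n <- 60
  lo <- rec_tbl("s1", runif(n, 500, 1000),
                overrides = list(Resistance = sample(0:1, n, TRUE),
                                 Depth = sample(0:1, n, TRUE)))
  hi <- rec_tbl("s2", runif(n, 900, 1800),
                overrides = list(Resistance = sample(2:3, n, TRUE),
                                 Depth = sample(1:2, n, TRUE)))
  train <- dplyr::bind_rows(lo, hi)
  part <- tibble::tibble(surgeon_id = c("s1", "s2"), cluster = 1:2)
  probe <- rec_tbl("sX", runif(200, 800, 1600),
                   overrides = list(Resistance = sample(2:3, 200, TRUE),
                                    Depth = sample(1:2, 200, TRUE)))
  routed <- assign_samples(probe, part, train)
  expect_gt(mean(routed == 2L), 0.5)
})

test_that("the Gaussian-mixture baseline separates well-separated groups", {
  sg <- surgeon_specs_default()[c(1, 2, 3, 6, 8, 9), ]
  sg$tenure_months <- 2L
  sg$records_per_month <- 20L
  # push the two groups far apart in operative speed
  sg$baseline_log_duration <- ifelse(sg$group == "experienced",
                                     log(500), log(2400))
  cfg <- default_config(surgeons = sg, seed = 23)
  ds <- generate_dataset(cfg)
  part <- gmm_partition(ds, k = 2, seed = 23)
  expect_equal(partition_ari(part, planted_partition(cfg)), 1)

  part_b <- gmm_partition(ds, k = 2, seed = 23)
  expect_identical(part$cluster, part_b$cluster) # seeded reproducibility

  part1 <- gmm_partition(ds, k = 1, seed = 23)
  expect_true(all(part1$cluster == 1L))
})

test_that("the group duration t-test matches its closed form", {
  ds <- dplyr::bind_rows(rec_tbl("s1", c(600, 900, 1200)),
                         rec_tbl("s2", c(600, 900, 1200)))
  part <- tibble::tibble(surgeon_id = c("s1", "s2"), cluster = c(1L, 2L))
  res <- group_duration_test(ds, part)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  ds2 <- dplyr::bind_rows(rec_tbl("s1", c(1, 2)), rec_tbl("s2", c(3, 4)))
  res2 <- group_duration_test(ds2, part)
  expect_equal(res2$statistic, -2 * sqrt(2), tolerance = 1e-6)

  # power under a +300 s novice shift
  set.seed(12)
  ds3 <- dplyr::bind_rows(
    rec_tbl("s1", rnorm(100, 900, 100)),
    rec_tbl("s2", rnorm(100, 1200, 100))
  )
  expect_lte(group_duration_test(ds3, part)$p_value, 0.05)

  dsc <- dplyr::bind_rows(rec_tbl("s1", c(5, 5)), rec_tbl("s2", c(5, 5)))
  expect_error(group_duration_test(dsc, part), "variance")
})

test_that("decoupling orders the planted groups by operative duration", {
  cfg <- default_config(seed = 29)
  ds <- generate_dataset(cfg)
  part <- decouple_surgeons(ds)
  res <- group_duration_test(ds, part)
  expect_lte(res$p_value, 0.05)
})
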