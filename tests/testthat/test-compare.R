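mk_stats <- function(up, down, all_ids) {
  dir <- rep("ns", length(all_ids))
  dir[match(up, all_ids)] <- "up"
  dir[match(down, all_ids)] <- "down"
  structure(data.frame(gene_id = all_ids, beta = 0, p = 1, fdr = 1,
                       direction = dir, stringsAsFactors = FALSE),
            class = c("gene_stats", "data.frame"))
}

test_that("partition reflects direction labels exactly", {
  ids <- paste0("g", 1:10)
  res <- list(A = mk_stats(c("g1", "g2"), "g3", ids),
              B = mk_stats(character(0), character(0), ids))
  part <- partition_by_direction(res)
  expect_setequal(part$A$up, c("g1", "g2"))
  expect_setequal(part$A$down, "g3")
  expect_length(part$B$up, 0)
  expect_length(intersect(part$A$up, part$A$down), 0)
  expect_equal(lengths(lapply(part, `[[`, "up")),
               c(A = 2L, B = 0L))
})

test_that("venn regions cover hand-checked examples", {
  ids <- paste0("g", 1:6)
  part <- partition_by_direction(list(
    A = mk_stats(c("g1", "g2", "g3"), character(0), ids),
    B = mk_stats(c("g2", "g3", "g4"), character(0), ids)))
  v <- venn_counts(part, "up")
  counts <- setNames(v$count, v$region)
  expect_equal(unname(counts["A"]), 1)
  expect_equal(unname(counts["B"]), 1)
  expect_equal(unname(counts["A&B"]), 2)

  same <- partition_by_direction(list(
    A = mk_stats(c("g1", "g2"), character(0), ids),
    B = mk_stats(c("g1", "g2"), character(0), ids)))
  v2 <- venn_counts(same, "up")
  expect_equal(v2$count[v2$region == "A&B"], 2)
  expect_true(all(v2$count[v2$region != "A&B"] == 0))
})

test_that("venn regions agree with a per-element bitmask oracle and
           marginals equal per-model totals", {
  set.seed(99)
  universe <- paste0("g", 1:500)
  for (rep in 1:5) {
    lists <- lapply(1:4, function(i) sample(universe, 50))
    names(lists) <- LETTERS[1:4]
    part <- structure(lapply(lists, function(s)
      list(up = s, down = character(0))), class = "direction_partition")
    v <- venn_counts(part, "up")
    # oracle: tabulate each element's membership pattern directly
    ids <- unique(unlist(lists))
    pattern <- vapply(ids, function(g)
      paste(LETTERS[1:4][vapply(lists, function(s) g %in% s, TRUE)],
            collapse = "&"), "")
    oracle <- table(pattern)
    for (i in seq_len(nrow(v))) {
      expected <- if (v$region[i] %in% names(oracle))
        as.integer(oracle[[v$region[i]]]) else 0L
      expect_identical(as.integer(v$count[i]), expected)
    }
    for (m in LETTERS[1:4]) {
      marg <- sum(v$count[vapply(strsplit(v$region, "&"),
                                 function(r) m %in% r, TRUE)])
      expect_identical(as.integer(marg), 50L)
    }
  }
  expect_error(venn_counts(structure(rep(list(list(up = "g1", down = NULL)), 7),
                                     names = letters[1:7],
                                     class = "direction_partition"), "up"),
               "> 6 models")
})

test_that("similarity ratios are row-normalized asymmetric overlaps", {
  ids <- paste0("g", 1:40)
  part <- partition_by_direction(list(
    A = mk_stats(paste0("g", 1:10), character(0), ids),
    B = mk_stats(paste0("g", 6:25), character(0), ids)))
  sm <- similarity_matrices(part)
  expect_equal(sm$pos["A", "B"], 5 / 10)
  expect_equal(sm$pos["B", "A"], 5 / 20)
  expect_equal(unname(diag(sm$pos)), c(1, 1))
  # empty down sets: zero rows, flagged, no NaN
  expect_true(all(sm$neg == 0))
  expect_true(all(sm$empty_rows$neg))
  expect_true(all(sm$pos >= 0 & sm$pos <= 1))

  disjoint <- partition_by_direction(list(
    A = mk_stats(paste0("g", 1:5), character(0), ids),
    B = mk_stats(paste0("g", 6:10), character(0), ids)))
  expect_equal(similarity_matrices(disjoint)$pos["A", "B"], 0)
})

test_that("similarity matrices are consistent with venn pairwise regions", {
  set.seed(41)
  universe <- paste0("g", 1:200)
  for (rep in 1:10) {
    sets <- lapply(1:3, function(i) sample(universe, sample(5:40, 1)))
    names(sets) <- c("A", "B", "C")
    part <- structure(lapply(sets, function(s)
      list(up = s, down = s[seq_len(min(3, length(s)))])),
      class = "direction_partition")
    sm <- similarity_matrices(part)
    for (a in names(sets)) for (b in names(sets)) {
      expect_equal(sm$pos[a, b],
                   length(intersect(sets[[a]], sets[[b]])) /
                     length(sets[[a]]))
    }
  }
})

test_that("sample scaling is definitional and clustering matches a naive
           average-linkage oracle", {
  set.seed(12)
  x <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  out <- scale_and_cluster(x, paste0("g", 1:8))
  expect_true(all(abs(colMeans(out$scaled)) < 1e-12))
  expect_true(all(abs(apply(out$scaled, 2, sd) - 1) < 1e-12))
  expect_equal(sort(out$sample_hclust$height),
               avg_linkage_heights_ref(dist(t(out$scaled))),
               tolerance = 1e-9)
  expect_equal(sort(out$gene_hclust$height),
               avg_linkage_heights_ref(dist(out$scaled)),
               tolerance = 1e-9)
})

test_that("identical samples merge first at height zero; constant columns warn", {
  x <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(9, 1, 4))
  rownames(x) <- paste0("g", 1:3)
  out <- scale_and_cluster(x, rownames(x))
  expect_equal(min(out$sample_hclust$height), 0, tolerance = 1e-12)
  expect_identical(out$sample_hclust$merge[1, ], c(-1L, -2L))
  y <- cbind(s1 = rep(2, 3), s2 = c(1, 2, 3))
  rownames(y) <- paste0("g", 1:3)
  expect_warning(scale_and_cluster(y, rownames(y)), "constant")
})

test_that("reference sign overlap matches a hand-tabulated toy table", {
  stats <- structure(
    data.frame(set = paste0("s", 1:8),
               est = c(2, 1, -1, 0.5, -2, 0.1, 3, -0.2),
               t_mod = 0, p = 0.01, fdr = c(0.01, 0.2, 0.01, 0.01, 0.01,
                                            0.2, 0.01, 0.01),
               direction = c("pos", "ns", "neg", "pos", "neg", "ns",
                             "pos", "neg"),
               m = 10, stringsAsFactors = FALSE),
    class = c("set_stats", "data.frame"))
  ref <- data.frame(set = c(paste0("s", 1:9), "s10"),
                    sign = c("+", "+", "-", "-", "+", "ns", "+", "-",
                             "+", "-"))
  ov <- reference_sign_overlap(stats, ref)
  # hand count: s1 +/pos C, s2 +/ns D, s3 -/neg C, s4 -/pos D,
  # s5 +/neg D, s6 ns excluded, s7 +/pos C, s8 -/neg C, s9 s10 missing
  expect_equal(unname(ov$summary["concordant"]), 4)
  expect_equal(unname(ov$summary["discordant"]), 3)
  expect_equal(unname(ov$summary["reference_ns"]), 1)
  expect_equal(unname(ov$summary["missing"]), 2)
  expect_identical(ov$table$concordance[1], "concordant")
})
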