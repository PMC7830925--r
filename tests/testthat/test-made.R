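test_that("with no observed transitions everything matches and stays active", {
  mod <- parallel_model()
  de <- data.frame(gene_id = c("gA", "gB", "x1"), d = 0L,
                   w = c(2, 3, 1))
  sol <- made_integrate(mod, de, f = 0.5)
  expect_equal(sol$objective_value, 6)
  expect_equal(sol$match_fraction, 1)
  expect_identical(sol$solver_status, "optimal")
  expect_true(all(sol$gene_states[, "WT"] == sol$gene_states[, "KO"]))
  expect_true(all(sol$reaction_states == 1))
})

test_that("a gene gating the only objective route cannot match", {
  mod <- chain_model(c(10, 5, 8))  # gA gates the single path
  de <- data.frame(gene_id = c("gA", "x1"), d = c(-1L, 1L), w = c(5, 2))
  sol <- made_integrate(mod, de, f = 0.5)
  # turning gA off kills the KO objective entirely, so only x1 matches
  expect_equal(sol$objective_value, 2)
  expect_equal(sol$gene_states["gA", ], c(WT = 1, KO = 1))
  expect_equal(sol$gene_states["x1", ], c(WT = 0, KO = 1))
})

test_that("a downregulated gene on a dispensable branch is switched off", {
  mod <- parallel_model(ub_a = 2, ub_b = 8)  # optimum 10
  de <- data.frame(gene_id = "gB", d = -1L, w = 4)
  lo <- made_integrate(mod, de, f = 0.2)  # threshold 2 = capacity of RA
  expect_equal(lo$objective_value, 4)
  expect_equal(lo$gene_states["gB", ], c(WT = 1, KO = 0))
  expect_equal(unname(lo$reaction_states["RB", ]), c(1, 0))
  hi <- made_integrate(mod, de, f = 0.5)  # threshold 5 needs branch B
  expect_equal(hi$objective_value, 0)
  expect_equal(hi$gene_states["gB", ], c(WT = 1, KO = 1))
})

test_that("solution reaction states always equal the GPR evaluation", {
  set.seed(31)
  for (r in 1:5) {
    mod <- random_toy_network(n_genes = 5, n_extra = 4, seed = 400 + r)
    de <- random_de_input(mod)
    sol <- made_integrate(mod, de, f = 0.3)
    for (cond in c("WT", "KO"))
      expect_equal(unname(sol$reaction_states[, cond]),
                   unname(reaction_states(mod, sol$gene_states[, cond])))
    expect_lte(sol$objective_value, sum(de$w) + 1e-9)
  }
})

test_that("branch-and-bound optimum equals exhaustive enumeration", {
  set.seed(57)
  for (r in 1:10) {
    mod <- random_toy_network(n_genes = sample(3:6, 1),
                              n_extra = sample(2:5, 1),
                              seed = 500 + r)
    de <- random_de_input(mod, n_extra = 2)
    sol <- made_integrate(mod, de, f = 0.3)
    expect_identical(sol$solver_status, "optimal")
    expect_equal(sol$objective_value, made_enumerate_ref(mod, de, 0.3),
                 tolerance = 1e-9, label = paste("instance", r))
  }
})

test_that("infeasible functionality demands are reported", {
  mod <- chain_model(c(0, 5, 8))  # uptake capped at zero: optimum 0
  de <- data.frame(gene_id = "gA", d = 0L, w = 1)
  expect_error(made_integrate(mod, de, f = 0.3), "no positive optimum")
})

test_that("reaction classification follows capacity and state overrides", {
  f_wt <- structure(data.frame(reaction = c("r1", "r2", "r3", "r4"),
                               state = c(1, 1, 1, 0),
                               lo = c(0, 0, 0, 0), hi = c(5, 5, 3, 0)),
                    class = c("fva_result", "data.frame"))
  f_ko <- structure(data.frame(reaction = c("r1", "r2", "r3", "r4"),
                               state = c(1, 0, 1, 1),
                               lo = c(0, 0, -4, 0), hi = c(8, 5, 0, 0)),
                    class = c("fva_result", "data.frame"))
  cls <- classify_reactions(f_wt, f_ko)
  expect_identical(cls$class, c("up", "down", "up", "up"))
  # r2: states 1 -> 0 overrides equal capacity; r3 capacity 3 -> 4 via |lo|
  # swap conditions: labels must swap exactly (antisymmetry)
  rev <- classify_reactions(f_ko, f_wt)
  map <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_identical(unname(map[cls$class]), rev$class)
  # tolerance branch
  f2 <- f_wt; f2$hi <- f_wt$hi + 1e-9; f2$state <- f_wt$state
  expect_identical(classify_reactions(f_wt, f2)$class[c(1, 3)],
                   c("unchanged", "unchanged"))
})

test_that("hypergeometric enrichment matches direct tail summation", {
  # spec-level spot check: N=20, K=5, n=6, k=4 -> 540/38760
  expect_equal(hyper_tail_ref(4, 5, 20, 6), 540 / 38760, tolerance = 1e-15)
  expect_equal(phyper(3, 5, 15, 6, lower.tail = FALSE), 540 / 38760,
               tolerance = 1e-12)
  set.seed(77)
  for (i in 1:200) {
    N <- sample(5:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 hyper_tail_ref(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("subsystem enrichment handles empty and degenerate directions", {
  mod <- toy_metabolic_model()
  cls <- data.frame(reaction = mod$reaction_ids, state_WT = 1,
                    state_KO = 1, M_WT = 1, M_KO = 1,
                    class = "unchanged", stringsAsFactors = FALSE)
  enr <- subsystem_enrichment(cls, mod)
  expect_true(all(enr$p == 1))
  expect_false(any(enr$significant))
  # k = 0 still gives P(X >= 0) = 1; K = N gives p = 1
  expect_equal(hyper_tail_ref(0, 3, 10, 4), 1)
  expect_equal(hyper_tail_ref(4, 10, 10, 4), 1)
  # a concentrated hit is significant
  cls$class[mod$subsystems[cls$reaction] == "Fatty acid beta-oxidation"] <-
    "down"
  enr2 <- subsystem_enrichment(cls, mod)
  row <- enr2[enr2$subsystem == "Fatty acid beta-oxidation" &
                enr2$direction == "down", ]
  expect_true(row$significant)
  expect_equal(row$p,
               hyper_tail_ref(row$k, row$K, row$N, row$n),
               tolerance = 1e-12)
})
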