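test_that("NTG and NSR reproduce hand-worked cases", {
  net <- bipartite_network(data.frame(
    mirna = c("m1", "m1", "m2", rep("m3", 5)),
    mrna = c("g1", "g2", "g2", sprintf("h%d", 1:5))))
  expect_equal(compute_ntg(net, "m1"), 2L)
  expect_equal(compute_ntg(net, "m3"), 5L)
  expect_equal(compute_nsr(net, "m1"), 1L)  # g2 is co-regulated by m2
  expect_equal(compute_nsr(net, "m2"), 0L)
  expect_equal(compute_nsr(net, "m3"), 5L)
  expect_error(compute_ntg(net, "mX"), "unknown miRNA")
  expect_error(compute_nsr(net, "mX"), "unknown miRNA")

  # every target co-regulated: NSR = 0 for all
  co <- bipartite_network(data.frame(mirna = rep(c("a", "b"), each = 3),
                                     mrna = rep(c("g1", "g2", "g3"), 2)))
  expect_equal(compute_nsr(co, "a"), 0L)
  expect_equal(compute_nsr(co, "b"), 0L)
})

test_that("vectorized features equal naive double-loop counts", {
  for (seed in 1:5) {
    net <- random_network(sample(5:25, 1), sample(30:150, 1),
                          runif(1, 0.02, 0.15), seed = seed)
    ft <- mirna_features(net)
    expect_identical(ft$ntg, vapply(ft$mirna, oracle_ntg, integer(1),
                                    net = net, USE.NAMES = FALSE))
    expect_identical(ft$nsr, vapply(ft$mirna, oracle_nsr, integer(1),
                                    net = net, USE.NAMES = FALSE))
    m1 <- net$mirna_nodes[1]
    expect_identical(compute_ntg(net, m1), oracle_ntg(net, m1))
    expect_identical(as.integer(compute_nsr(net, m1)), oracle_nsr(net, m1))
    expect_true(all(ft$nsr <= ft$ntg))
    expect_true(all(ft$ratio >= 0 & ft$ratio <= 1))
  }
})

test_that("removing an edge never increases NTG; extra regulators never raise NSR", {
  net <- random_network(10, 60, 0.1, seed = 9)
  ft <- mirna_features(net)
  drop1 <- bipartite_network(net$edges[-1, ], mirna_nodes = net$mirna_nodes,
                             mrna_nodes = net$mrna_nodes)
  ft2 <- mirna_features(drop1)
  expect_true(all(ft2$ntg <= ft$ntg))
  # add a second regulator to a single-line target of the first miRNA
  single <- names(which(table(net$edges$mrna) == 1))
  tgt <- intersect(net$edges$mrna[net$edges$mirna == net$mirna_nodes[1]],
                   single)
  skip_if(length(tgt) == 0)
  other <- net$mirna_nodes[2]
  aug <- bipartite_network(rbind(net$edges,
                                 data.frame(mirna = other, mrna = tgt[1])))
  expect_equal(compute_nsr(aug, net$mirna_nodes[1]),
               compute_nsr(net, net$mirna_nodes[1]) - 1L)
})

test_that("NSR/NTG ratio validates and rounds to 4 decimals", {
  expect_equal(compute_ratio(69, 15), 0.2174)
  expect_equal(compute_ratio(50, 14), 0.28)
  expect_equal(compute_ratio(7, 0), 0)
  expect_equal(compute_ratio(0, 0), 0)
  expect_error(compute_ratio(3, 5), "NSR exceeds NTG")
  expect_error(compute_ratio(-1, 0), "nonnegative")
})

test_that("signed-rank p-values match full sign-pattern enumeration", {
  # all-positive n = 3, one-sided: p = 1/8
  r <- wilcoxon_signed_rank(c(1, 2, 3), alternative = "greater")
  expect_equal(r$p.value, 0.125)
  expect_true(r$exact)
  # symmetric +/- pairs: two-sided p = 1
  expect_equal(wilcoxon_signed_rank(c(2, -2, 5, -5))$p.value, 1)
  # zeros are dropped; all-zero input is degenerate
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, 3),
                                    alternative = "greater")$n, 3L)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "degenerate")

  set.seed(14)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    skip_if(length(d) == 0)
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(wilcoxon_signed_rank(d, alt)$p.value,
                   oracle_signed_rank_p(d, alt),
                   info = sprintf("i=%d alt=%s", i, alt))
    }
  }
})

test_that("tied differences fall back to the corrected normal approximation", {
  d <- c(1, 1, -1, 2, 2, -3, 4, 4, 4, -2)
  r <- wilcoxon_signed_rank(d, alternative = "less")
  expect_false(r$exact)
  ref <- suppressWarnings(wilcox.test(d, alternative = "less",
                                      correct = TRUE))
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("prioritization flags only clear topological outliers", {
  # identical metric values: nothing prioritized
  flat <- data.frame(mirna = sprintf("m%02d", 1:12), ntg = 5L, nsr = 2L,
                     ratio = 0.4)
  out <- prioritize(flat)
  expect_false(any(out$prioritized))

  # one miRNA strictly above 30 others on all metrics: prioritized
  set.seed(2)
  bg <- data.frame(mirna = sprintf("m%02d", 1:30),
                   ntg = sample(5:15, 30, TRUE))
  bg$nsr <- pmin(bg$ntg, sample(0:4, 30, TRUE))
  bg$ratio <- compute_ratio(bg$ntg, bg$nsr)
  top <- data.frame(mirna = "m99", ntg = 40L, nsr = 30L, ratio = 0.75)
  out <- prioritize(rbind(bg, top))
  expect_true(out$prioritized[out$mirna == "m99"])
  expect_true(all(out[out$mirna == "m99", c("p_ntg", "p_nsr", "p_ratio")] <
                    0.05))

  expect_error(prioritize(flat[1:5, ]), "insufficient network")
})

test_that("percentile variant approximates a 95th-percentile cut", {
  set.seed(8)
  ft <- data.frame(mirna = sprintf("m%02d", 1:40), ntg = 1:40, nsr = 1:40,
                   ratio = seq(0.01, 0.4, length.out = 40))
  out <- prioritize(ft, method = "percentile")
  # with 39 cohort values, only the maximum reaches (1+0)/40 < 0.05
  expect_true(all(out$prioritized == (seq_len(40) == 40)))
  expect_equal(out$p_ntg[40], 1 / 40)
  expect_equal(out$p_ntg[39], 2 / 40)
})

test_that("planted biomarkers are recovered by prioritization", {
  hits <- sapply(1:10, function(seed) {
    study <- generate_synthetic_study(small_config(seed = seed))
    net <- extract_condition_network(study$network,
                                     study$truth$planted_de_mirnas_occurrence,
                                     study$truth$planted_de_mrnas_occurrence)
    ft <- prioritize(mirna_features(net))
    all(study$truth$planted_biomarkers %in% ft$mirna[ft$prioritized])
  })
  expect_gte(sum(hits), 9)
})

test_that("condition intersection and shared regulations work on hand fixtures", {
  expect_identical(intersect_conditions(c("a", "b", "c"), c("d", "c", "b")),
                   c("b", "c"))
  expect_identical(intersect_conditions(c("a"), c("b")), character(0))

  occ <- bipartite_network(data.frame(mirna = c("m1", "m1", "m2"),
                                      mrna = c("g1", "g2", "g3")))
  prog <- bipartite_network(data.frame(mirna = c("m1", "m1", "m2"),
                                       mrna = c("g1", "g4", "g3")))
  sh <- shared_regulations(occ, prog, c("m1", "m2"))
  expect_equal(sh$n_regulations, 2L)
  expect_setequal(sh$edges$mrna, c("g1", "g3"))
  expect_equal(sh$n_mrna, 2L)
  # a shared miRNA absent from one network contributes nothing
  sh2 <- shared_regulations(occ, prog, c("m1", "mX"))
  expect_equal(sh2$n_regulations, 1L)
  # identical networks return all edges of the shared miRNAs
  sh3 <- shared_regulations(occ, occ, c("m1", "m2"))
  expect_equal(sh3$n_regulations, 3L)
  # union mode keeps edges present in either network
  sh4 <- shared_regulations(occ, prog, c("m1", "m2"), mode = "union")
  expect_equal(sh4$n_regulations, 4L)
  expect_error(shared_regulations(occ, prog, character(0)), "nonempty")
})
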