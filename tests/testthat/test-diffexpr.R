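test_that("two-group fit matches exact arithmetic and a naive oracle", {
  vals <- rbind(f1 = c(1, 1, 3, 3),
                f2 = c(2, 2, 2, 2))
  x <- expression_matrix(
    matrix(vals, 2, 4, dimnames = list(c("f1", "f2"), sprintf("s%d", 1:4))),
    c(s1 = "normal", s2 = "normal", s3 = "pPCa", s4 = "mPCa"))
  fit <- fit_two_group(x, make_contrast("occurrence"))
  expect_equal(fit$log_fc, c(2, 0))
  expect_equal(fit$s2, c(0, 0))
  expect_equal(fit$df_resid, c(2, 2))
  expect_equal(fit$v, rep(1 / 2 + 1 / 2, 2))

  x2 <- small_matrix(n_feat = 50, seed = 42)
  ctr <- make_contrast("progression")
  fit2 <- fit_two_group(x2, ctr)
  for (i in seq_len(nrow(x2$values))) {
    a <- x2$values[i, x2$groups == "pPCa"]
    b <- x2$values[i, x2$groups == "mPCa"]
    expect_equal(fit2$log_fc[i], mean(b) - mean(a))
    expect_equal(fit2$s2[i],
                 (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
                   (length(a) + length(b) - 2))
  }
})

test_that("a contrast side with fewer than 2 samples is an error", {
  x <- small_matrix(n_per = c(4, 5, 1))
  expect_error(fit_two_group(x, make_contrast("progression")),
               "insufficient replication")
  expect_silent(invisible(fit_two_group(x, make_contrast("occurrence"))))
})

test_that("forcing d0 = 0 recovers the ordinary pooled two-sample t", {
  x <- small_matrix(n_feat = 30, seed = 3)
  fit <- fit_two_group(x, make_contrast("occurrence"))
  mod <- ebayes_moderate(fit, d0 = 0)
  for (i in 1:5) {
    a <- x$values[i, x$groups == "normal"]
    b <- x$values[i, x$groups != "normal"]
    tt <- t.test(b, a, var.equal = TRUE)
    expect_equal(mod$table$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(mod$table$p_raw[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("identical residual variances drive d0 to infinity", {
  fit <- data.frame(feature = sprintf("f%d", 1:20), log_fc = rnorm(20),
                    s2 = rep(2, 20), df_resid = 10, v = 0.2)
  mod <- ebayes_moderate(fit)
  expect_identical(mod$prior$d0, Inf)
  # moment fit's log-scale bias correction: s0^2 = s2 * (d/2)/exp(digamma(d/2))
  expect_equal(mod$prior$s0_sq, 2 * (10 / 2) / exp(digamma(5)),
               tolerance = 1e-10)
  expect_equal(unique(mod$table$s2), 2)
  expect_equal(mod$table$p_raw, 2 * pnorm(-abs(mod$table$t_mod)))
})

test_that("moment estimator recovers a planted variance prior", {
  # variances drawn from the scaled-F sampling model with d0 = 4, s0^2 = 1
  est <- t(sapply(1:20, function(s) {
    set.seed(s)
    d <- 10
    truevar <- 4 / rchisq(200, 4)
    s2 <- truevar * rchisq(200, d) / d
    fit <- data.frame(feature = sprintf("f%d", 1:200), log_fc = 0, s2 = s2,
                      df_resid = d, v = 0.2)
    pr <- ebayes_moderate(fit)$prior
    c(pr$d0, pr$s0_sq)
  }))
  expect_true(all(est[, 1] >= 2 & est[, 1] <= 8))
  expect_true(all(est[, 2] >= 0.7 & est[, 2] <= 1.4))
})

test_that("moderated statistics agree with the limma reference", {
  skip_if_not_installed("limma")
  x <- small_matrix(n_feat = 120, n_per = c(8, 12, 6), shift = 1.5,
                    n_shift = 20, seed = 10)
  ctr <- make_contrast("occurrence")
  fit <- fit_two_group(x, ctr)
  mod <- ebayes_moderate(fit)
  design <- cbind(1, as.integer(x$groups != "normal"))
  lf <- limma::eBayes(limma::lmFit(x$values, design))
  expect_equal(mod$prior$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(mod$prior$s0_sq, lf$s2.prior, tolerance = 1e-6)
  expect_equal(mod$table$t_mod, unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(mod$table$p_raw, unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("shrunken variances lie between the prior and the observed", {
  x <- small_matrix(n_feat = 80, seed = 6)
  fit <- fit_two_group(x, make_contrast("occurrence"))
  mod <- ebayes_moderate(fit)
  pr <- mod$prior
  s2_post <- (pr$d0 * pr$s0_sq + fit$df_resid * fit$s2) /
    (pr$d0 + fit$df_resid)
  lo <- pmin(pr$s0_sq, fit$s2); hi <- pmax(pr$s0_sq, fit$s2)
  expect_true(all(s2_post >= lo - 1e-12 & s2_post <= hi + 1e-12))
})

test_that("prior estimation demands enough positive-variance features", {
  fit <- data.frame(feature = sprintf("f%d", 1:12), log_fc = 0,
                    s2 = c(rep(0, 8), rep(1, 4)), df_resid = 4, v = 0.5)
  expect_error(ebayes_moderate(fit), "at least 10 features")
})

test_that("BH adjustment matches the step-up definition and its properties", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(21)
  for (i in 1:5) {
    p <- runif(37)^2
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
    # idempotence: re-adjusting adjusted values never lowers them
    expect_true(all(bh_adjust(q) >= q - 1e-15))
  }
  expect_error(bh_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.2, NA)), "\\[0, 1\\]")
})

test_that("probe collapse keeps each gene's most significant probe", {
  tab <- data.frame(feature = c("p1", "p2", "p3", "p4", "p5"),
                    log_fc = c(1, -2, 0.5, 0.5, 3),
                    p_raw = c(0.3, 0.001, 0.05, 0.05, 0.01),
                    stringsAsFactors = FALSE)
  map <- data.frame(probe = c("p1", "p2", "p3", "p4"),
                    gene = c("gA", "gA", "gB", "gB"))
  expect_message(out <- collapse_probes(tab, map), "1 unmapped")
  expect_setequal(out$feature, c("gA", "gB"))
  expect_equal(out$probe[out$feature == "gA"], "p2")
  # tie on p_raw and |log_fc| resolved lexicographically
  expect_equal(out$probe[out$feature == "gB"], "p3")
  expect_error(collapse_probes(tab, map[0, ]), "nonempty")

  # brute-force group-by-gene argmin oracle on a random fixture
  set.seed(33)
  tab2 <- data.frame(feature = sprintf("pr%02d", 1:40),
                     log_fc = rnorm(40), p_raw = runif(40))
  map2 <- data.frame(probe = tab2$feature,
                     gene = sample(sprintf("G%d", 1:12), 40, TRUE))
  out2 <- collapse_probes(tab2, map2)
  for (g in unique(map2$gene)) {
    rows <- tab2[tab2$feature %in% map2$probe[map2$gene == g], ]
    expect_equal(out2$p_raw[out2$feature == g], min(rows$p_raw))
  }
})

test_that("DE selection uses a strict threshold", {
  tab <- data.frame(feature = c("a", "b", "c"),
                    p_adj = c(0.049999, 0.05, 1),
                    direction = c("Up", "Down", "Up"))
  sel <- select_de(tab)
  expect_identical(sel$feature, "a")
  expect_identical(select_de(data.frame(feature = "x", p_adj = 1))$feature,
                   character(0))
})

test_that("full DE run flags planted features and controls the null", {
  x <- small_matrix(n_feat = 100, n_per = c(10, 14, 8), shift = 3,
                    n_shift = 15, sd = 0.5, seed = 12)
  de <- run_de(x, make_contrast("occurrence"))
  expect_true(all(de$is_de[1:15]))
  expect_true(all(de$direction[1:15] == "Up"))
  expect_lte(sum(de$is_de[16:100]), 3)
  expect_true(all(de$p_adj >= de$p_raw))
})
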