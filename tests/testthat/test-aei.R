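test_that("build_design multiplies size factors, proportions and cell sizes", {
  P <- matrix(c(0.5, 0.25, 0.5, 0.75), nrow = 2,
              dimnames = list(c("s1", "s2"), c("t1", "t2")))
  D <- build_design(c(s1 = 1, s2 = 2), P)
  expect_equal(unname(D), rbind(c(0.5, 0.5), c(0.5, 1.5)))
  # with row-normalized proportions and no cell sizes the rows sum to m_j
  expect_equal(unname(rowSums(D)), c(1, 2))
  # K = 1, m = 1, p = 1 -> a column of ones
  one <- build_design(c(a = 1), matrix(1, 1, 1, dimnames = list("a", "t")))
  expect_equal(unname(one[, 1]), 1)
  # cell sizes rescale columns
  Ds <- build_design(c(s1 = 1, s2 = 2), P, cell_sizes = c(t1 = 10, t2 = 1))
  expect_equal(unname(Ds[, "t1"]), 10 * unname(D[, "t1"]))
  expect_equal(unname(Ds[, "t2"]), unname(D[, "t2"]))
})

test_that("build_design validates samples and positivity", {
  P <- matrix(0.5, 2, 2, dimnames = list(c("s1", "sX"), c("t1", "t2")))
  expect_error(build_design(c(s1 = 1), P), "sX")
  P2 <- matrix(0.5, 1, 2, dimnames = list("s1", c("t1", "t2")))
  expect_error(build_design(c(s1 = 0), P2), "positive")
  expect_error(build_design(c(s1 = 1), P2, cell_sizes = c(t1 = 1)), "t2")
})

test_that("noiseless forward-constructed SNPs recover coefficients exactly", {
  D <- random_design(40, 3, seed = 101)
  theta <- c(30, -55, 12)
  alpha <- 7
  y <- alpha + drop(D %*% theta)
  tab <- counts_from_y(y, rownames(D))
  fit <- test_aei(tab, D)
  got <- fit$results
  y_int <- tab$ref_count - tab$alt_count   # rounding altered y slightly
  oracle <- ols_oracle(y_int[match(rownames(D), tab$sample_id)],
                       cbind(1, D))
  expect_equal(got$estimate, unname(oracle$coef[-1]), tolerance = 1e-8)
  expect_equal(fit$snp$alpha, unname(oracle$coef[1]), tolerance = 1e-8)
})

test_that("estimates, SEs, t and p match a normal-equations oracle", {
  for (seed in c(5, 17, 91)) {
    D <- random_design(30, 3, seed = seed)
    withr::with_seed(seed + 1, {
      y <- round(rnorm(30, sd = 40) + drop(D %*% c(20, -10, 5)))
    })
    tab <- counts_from_y(y, rownames(D))
    fit <- test_aei(tab, D)
    y_al <- (tab$ref_count - tab$alt_count)[match(rownames(D),
                                                  tab$sample_id)]
    oracle <- ols_oracle(y_al, cbind(1, D))
    expect_equal(fit$results$estimate, unname(oracle$coef[-1]),
                 tolerance = 1e-10)
    expect_equal(fit$results$se, unname(oracle$se[-1]), tolerance = 1e-10)
    expect_equal(fit$results$statistic, unname(oracle$t[-1]),
                 tolerance = 1e-10)
    expect_equal(fit$results$p, unname(oracle$p[-1]), tolerance = 1e-10)
    expect_equal(fit$results$df[1], oracle$df)
    expect_equal(fit$snp$sigma2, oracle$sigma2, tolerance = 1e-10)
  }
})

test_that("swapping ref and alt labels negates estimates, keeps p-values", {
  D <- random_design(25, 2, seed = 31)
  withr::with_seed(32, y <- round(rnorm(25, sd = 30) + drop(D %*% c(15, -8))))
  tab <- counts_from_y(y, rownames(D))
  swapped <- tab
  swapped$ref_count <- tab$alt_count
  swapped$alt_count <- tab$ref_count
  f1 <- test_aei(tab, D)
  f2 <- test_aei(swapped, D)
  expect_equal(f2$results$estimate, -f1$results$estimate)
  expect_equal(f2$snp$alpha, -f1$snp$alpha)
  expect_equal(f2$results$p, f1$results$p)
  expect_equal(abs(f2$results$statistic), abs(f1$results$statistic))
})

test_that("degenerate and under-determined SNPs get codes, not p-values", {
  D <- random_design(10, 2, seed = 44)
  zero <- make_counts(samples = rownames(D), ref = rep(5L, 10),
                      alt = rep(5L, 10))
  fit <- test_aei(zero, D)
  expect_equal(fit$results$code, rep("degenerate", 2))
  expect_equal(fit$results$estimate, c(0, 0))
  expect_equal(fit$snp$alpha, 0)
  expect_true(all(is.na(fit$results$p)))

  tiny <- make_counts(samples = rownames(D)[1:3], ref = c(4L, 9L, 2L),
                      alt = c(5L, 1L, 8L))
  fit2 <- test_aei(tiny, D)   # 3 individuals < K + 2
  expect_equal(fit2$results$code, rep("low_n", 2))

  # duplicated proportion columns: exact collinearity
  Dc <- cbind(D, t3 = D[, 2])
  withr::with_seed(9, yr <- round(rnorm(10, sd = 20)))
  fit3 <- test_aei(counts_from_y(yr, rownames(D)), Dc)
  expect_equal(fit3$results$code, rep("collinear", 3))
})

test_that("BH adjustment matches hand-worked step-up values", {
  expect_equal(adjust_fdr(0.01), 0.01)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(2, p <- runif(50))
  q <- adjust_fdr(p)
  expect_true(all(q >= p))
  # NA propagation without counting NAs as tests
  q2 <- adjust_fdr(c(0.01, NA, 0.02))
  expect_true(is.na(q2[2]))
  expect_equal(q2[c(1, 3)], adjust_fdr(c(0.01, 0.02)))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("joint and per-cell-type FDR scopes differ as documented", {
  D <- random_design(30, 2, seed = 71)
  withr::with_seed(72, {
    tabs <- lapply(1:6, function(i) {
      counts_from_y(round(rnorm(30, sd = 30)), rownames(D),
                    snp = paste0("rs", i), gene = paste0("g", i))
    })
  })
  tab <- do.call(rbind, tabs)
  joint <- test_aei(tab, D, fdr_scope = "joint")
  per <- test_aei(tab, D, fdr_scope = "per_celltype")
  r <- joint$results
  expect_equal(joint$results$q, adjust_fdr(r$p))
  sel <- per$results$cell_type == "ct1"
  expect_equal(per$results$q[sel], adjust_fdr(r$p[sel]))
})

test_that("bulk GLM reduces to the logit of the pooled fraction", {
  one <- make_counts(samples = "a", ref = 15L, alt = 5L)
  res <- bulk_glm_test(one)
  expect_equal(res$estimate, log(3), tolerance = 1e-8)

  bal <- make_counts(samples = letters[1:6], ref = rep(10L, 6),
                     alt = rep(10L, 6))
  res2 <- bulk_glm_test(bal)
  expect_equal(res2$estimate, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1, tolerance = 1e-8)

  sep <- make_counts(samples = c("a", "b"), ref = c(5L, 8L), alt = c(0L, 0L))
  expect_equal(bulk_glm_test(sep)$code, "separation")
})

test_that("bulk GLM matches an independent IRLS oracle", {
  for (seed in c(3, 23)) {
    withr::with_seed(seed, {
      n <- 20
      tot <- rpois(n, 60) + 10L
      ref <- rbinom(n, tot, 0.58)
    })
    tab <- make_counts(samples = sprintf("i%02d", 1:20), ref = ref,
                       alt = tot - ref)
    res <- bulk_glm_test(tab)
    oracle <- irls_logit_oracle(ref, tot - ref, matrix(1, 20, 1))
    expect_equal(res$estimate, oracle$coef[1], tolerance = 1e-8)
    expect_equal(res$se, oracle$se[1], tolerance = 1e-8)
    expect_equal(res$z, oracle$z[1], tolerance = 1e-8)
  }
})

test_that("opposite-direction cell-type effects cancel in bulk, not per type", {
  # two cell types imbalanced in opposite directions; allelic fractions
  # constructed so the pooled reference fraction is exactly balanced
  withr::with_seed(55, {
    n <- 60
    p1 <- rbeta(n, 4, 4)
    m <- exp(rnorm(n, 0, 0.2))
    P <- cbind(t1 = p1, t2 = 1 - p1)
    rownames(P) <- sprintf("i%02d", 1:n)
    D <- P * m
    tot <- rep(400L, n)
    contrast <- p1 - (1 - p1)
    frac <- 0.5 + 0.25 * (contrast - mean(contrast))
    ref <- as.integer(round(tot * frac))
  })
  tab <- make_counts(samples = rownames(P), ref = ref, alt = tot - ref)
  bulk_res <- bulk_glm_test(tab)
  pooled <- sum(ref) / sum(tot)
  expect_lt(abs(pooled - 0.5), 0.005)
  expect_gt(bulk_res$p, 0.01)
  fit <- test_aei(tab, D)
  expect_true(all(fit$results$p < 1e-6))
  expect_gt(fit$results$estimate[1], 0)
  expect_lt(fit$results$estimate[2], 0)
})

test_that("resampling enrichment matches the hypergeometric tail on a toy set", {
  # 40-gene universe: 10 hits, 30 background, reference set of 12
  universe <- sprintf("g%02d", 1:40)
  hits <- universe[1:10]
  background <- universe[11:40]
  reference <- universe[c(1:4, 15:22)]   # 4 of 10 hits, 8 of 30 background
  res <- enrichment_resampling(hits, background, reference, seed = 42)
  expect_equal(res$observed, 0.4)
  # exact enumeration: P(X >= 4), X ~ Hypergeom(8 marked, 22 unmarked, 10)
  exact <- phyper(3, 8, 22, 10, lower.tail = FALSE)
  mc_se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(res$p - exact), 3 * mc_se)
  expect_identical(formals(enrichment_resampling)$n_resamples, 10000L)
})

test_that("enrichment test handles saturation and rejects bad sets", {
  hits <- c("a", "b")
  background <- c("c", "d", "e")
  res <- enrichment_resampling(hits, background,
                               reference_set = c(hits, background),
                               n_resamples = 200, seed = 1)
  expect_equal(res$observed, 1)
  expect_equal(res$p, 1)
  expect_error(enrichment_resampling(c("a"), c("a", "b"), "a"), "disjoint")
  expect_error(enrichment_resampling(c("a", "b", "c"), c("d"), "a"),
               "at least as many")
})

test_that("fit objects print, summarize and export coherently", {
  D <- random_design(30, 2, seed = 61)
  withr::with_seed(62, {
    tab <- rbind(
      counts_from_y(round(rnorm(30, sd = 25)), rownames(D), snp = "rs1",
                    gene = "g1"),
      counts_from_y(round(100 * D[, 1] + rnorm(30, sd = 10)), rownames(D),
                    snp = "rs2", gene = "g2"))
  })
  fit <- test_aei(tab, D)
  expect_s3_class(fit, "aei_fit")
  expect_output(print(fit), "SNPs: 2")
  s <- summary(fit)
  expect_equal(sum(s$per_cell_type$tested), 4)
  cf <- coef(fit)
  expect_equal(dim(cf), c(2L, 2L))
  expect_equal(cf["rs2", "ct1"],
               fit$results$estimate[fit$results$snp_id == "rs2" &
                                      fit$results$cell_type == "ct1"])
  expect_equal(as.data.frame(fit), fit$results)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(fit, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 4L)
})
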