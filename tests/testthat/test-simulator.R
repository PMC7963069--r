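small_cfg <- function(...) {
  sim_config(n_individuals = 20L, n_cells = 500L, n_snps = 60L, ...)
}

test_that("configuration defaults encode the benchmark study conditions", {
  cfg <- sim_config()
  expect_equal(cfg$n_individuals, 60L)
  expect_equal(cfg$n_cells, 5000L)
  expect_equal(cfg$n_cell_types, 6L)
  expect_equal(cfg$n_snps, 11300L)
  expect_equal(cfg$n_total, 200L)
  expect_equal(cfg$daei_fraction, 0.5)
  expect_equal(cfg$opposite_fraction, 0.30)
  expect_equal(sum(cfg$dirichlet_mean), 1)
  expect_error(sim_config(aei_truncation = 0.7), "0.5")
  expect_error(sim_config(dirichlet_mean = c(0.5, 0.4, 0.2, 0.1, 0.1, 0.1)),
               "sum to 1")
})

test_that("reference profiles are deterministic with valid support", {
  p1 <- sample_reference_profile(50, 4, seed = 9)
  p2 <- sample_reference_profile(50, 4, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$means > 0))
  expect_true(all(p1$expressed_fraction >= 0 & p1$expressed_fraction <= 1))
  # log-mean of the draws concentrates on the requested location
  big <- sample_reference_profile(20000, 5, meanlog = log(0.2), sdlog = 0.8,
                                  gene_sdlog = 0.6, seed = 3)
  target <- log(0.2)
  se <- sqrt(0.8^2 + 0.6^2) / sqrt(length(big$means))
  expect_lt(abs(mean(log(big$means)) - target), 3 * se * sqrt(5))
})

test_that("AEI levels follow the truncated-gamma construction", {
  major <- rep(1L, 500)
  nonmajor <- rep(2L, 500)
  lev <- sample_aei_levels(500, "one-cell-type", major = major,
                           nonmajor = nonmajor,
                           cell_types = c("t1", "t2", "t3"), seed = 4)
  expect_true(all(lev$aei[, 2:3] == 0.5))
  expect_true(all(lev$aei[, 1] > 0.5 & lev$aei[, 1] < 1))
  expect_true(all(is.na(lev$opposite)))

  lev2 <- sample_aei_levels(500, "two-cell-types", opposite_fraction = 0.3,
                            major = major, nonmajor = nonmajor,
                            cell_types = c("t1", "t2", "t3"), seed = 5)
  expect_equal(sum(lev2$opposite), 150)
  opp <- lev2$opposite
  expect_equal(unname(lev2$aei[opp, 1] + lev2$aei[opp, 2]),
               rep(1, sum(opp)))
  expect_true(all(lev2$aei[!opp, 2] > 0.5))
  expect_error(sample_aei_levels(10, truncation = 0.6, major = rep(1L, 10),
                                 nonmajor = rep(2L, 10),
                                 cell_types = c("a", "b")), "0.5")
})

test_that("simulated datasets are internally consistent and deterministic", {
  cfg <- small_cfg(seed = 15)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$bulk, sim2$bulk)

  # bulk totals equal ref + alt per (gene, individual)
  tot <- with(sim1$counts, tapply(ref_count + alt_count,
                                  list(gene_id, sample_id), sum))
  expect_equal(unname(tot[rownames(sim1$bulk), colnames(sim1$bulk)]),
               unname(sim1$bulk), ignore_attr = TRUE)
  expect_equal(unname(rowSums(sim1$proportions)), rep(1, 20))
  expect_true(all(sim1$truth$aei >= 0.5 | sim1$truth$aei == 0.5 |
                    sim1$truth$aei < 1))
  # major carries the AEI in scenario 1
  gi <- seq_len(nrow(sim1$truth$aei))
  maj_idx <- match(sim1$truth$major, colnames(sim1$truth$aei))
  expect_true(all(sim1$truth$aei[cbind(gi, maj_idx)] > 0.5))
})

test_that("cell-count allocation and Dirichlet draws behave as stated", {
  alloc <- ctaei:::allocate_cells(c(0.301, 0.299, 0.4), 10)
  expect_equal(sum(alloc), 10)
  expect_equal(alloc, c(3L, 3L, 4L))
  cfg <- sim_config(n_individuals = 400L, n_cells = 100L, n_snps = 2L,
                    seed = 8)
  sim <- simulate_dataset(cfg)
  emp <- colMeans(sim$proportions)
  se <- sqrt(cfg$dirichlet_mean * (1 - cfg$dirichlet_mean) /
               (cfg$dirichlet_concentration + 1)) / sqrt(400)
  expect_true(all(abs(emp - cfg$dirichlet_mean) < 4 * se))
})

test_that("without AEI the pooled reference fraction is balanced", {
  cfg <- sim_config(n_individuals = 30L, n_cells = 800L, n_snps = 150L,
                    aei_scale = 1e-9, seed = 23)
  sim <- simulate_dataset(cfg)
  ref <- sum(sim$counts$ref_count)
  tot <- ref + sum(sim$counts$alt_count)
  se <- sqrt(0.25 / tot)
  expect_lt(abs(ref / tot - 0.5), 3 * se + 1e-3)
})

test_that("two-condition runs encode the differential-AEI design", {
  cfg <- small_cfg(n_total = 30L, case_ratio = 0.3, delta_aei = 0.1,
                   seed = 77)
  sim <- simulate_two_condition(cfg)
  expect_equal(sum(sim$condition == 1), 9)
  expect_equal(length(sim$condition), 30)
  tr <- sim$truth
  gi <- seq_len(nrow(tr$aei_healthy))
  maj <- match(tr$major, colnames(tr$aei_healthy))
  d <- tr$aei_diseased[cbind(gi, maj)] - tr$aei_healthy[cbind(gi, maj)]
  expect_equal(unname(d[tr$daei]), rep(0.1, sum(tr$daei)))
  expect_true(all(d[!tr$daei] == 0))
  expect_true(all(tr$aei_diseased < 1))
  # entries outside the major cell type never differ between conditions
  ah <- tr$aei_healthy; ad <- tr$aei_diseased
  ah[cbind(gi, maj)] <- NA; ad[cbind(gi, maj)] <- NA
  expect_equal(ah, ad)

  # delta = 0 collapses the two groups to identical generative parameters
  cfg0 <- small_cfg(n_total = 30L, delta_aei = 0, seed = 78)
  sim0 <- simulate_two_condition(cfg0)
  expect_equal(sim0$truth$aei_healthy, sim0$truth$aei_diseased)
})

test_that("diseased-minus-healthy allelic gap approximates delta", {
  cfg <- sim_config(n_individuals = 60L, n_cells = 2000L, n_snps = 250L,
                    n_total = 120L, delta_aei = 0.2, daei_fraction = 1,
                    seed = 91)
  sim <- simulate_two_condition(cfg)
  # restrict to genes where the major type dominates the bulk signal
  tr <- sim$truth
  healthy <- names(sim$condition)[sim$condition == 0]
  diseased <- names(sim$condition)[sim$condition == 1]
  frac <- function(ids) {
    sel <- sim$counts$sample_id %in% ids
    tapply(sim$counts$ref_count[sel], sim$counts$gene_id[sel], sum) /
      tapply(sim$counts$ref_count[sel] + sim$counts$alt_count[sel],
             sim$counts$gene_id[sel], sum)
  }
  gap <- frac(diseased) - frac(healthy)
  # bulk gap is delta attenuated by the major type's molecular share;
  # it must be clearly positive and below delta
  expect_gt(mean(gap, na.rm = TRUE), 0.02)
  expect_lt(mean(gap, na.rm = TRUE), 0.2)
})

test_that("read-depth scale increases coverage monotonically", {
  covs <- vapply(c(0.5, 1, 2), function(ds) {
    mean(simulate_dataset(small_cfg(depth_scale = ds, seed = 33))$bulk)
  }, 0)
  expect_true(all(diff(covs) > 0))
})

test_that("benchmark scoring matches a hand tally on a labelled toy", {
  genes <- sprintf("g%02d", 1:4)
  cts <- c("t1", "t2")
  aei <- matrix(0.5, 4, 2, dimnames = list(genes, cts))
  aei[, 1] <- c(0.65, 0.75, 0.95, 0.5)   # g4 null everywhere
  truth <- structure(list(aei = aei, major = rep("t1", 4),
                          nonmajor = rep("t2", 4),
                          opposite = rep(NA, 4)), class = "sim_truth")
  results <- data.frame(
    snp_id = rep(sub("g", "rs", genes), each = 2),
    gene_id = rep(genes, each = 2),
    cell_type = rep(cts, 4),
    n = 30, estimate = 1, se = 1, statistic = 1, df = 27,
    p = c(0.01, 0.2,    # g1: t1 detected, t2 null not rejected
          0.3, 0.01,    # g2: t1 missed, t2 false positive
          0.001, 0.9,   # g3: t1 detected
          0.5, 0.04),   # g4: null, t2 false positive
    code = "ok", stringsAsFactors = FALSE)
  results$q <- adjust_fdr(results$p)
  fit <- structure(list(results = results, cell_types = cts, K = 2L),
                   class = "aei_fit")
  ev <- evaluate_benchmark(fit, truth, alpha = 0.05,
                           bins = c(0.5, 0.7, 1))
  # power: t1 bin [0.5,0.7): g1 (0.65) detected -> 1
  expect_equal(ev$power$power[ev$power$cell_type == "t1" &
                                ev$power$bin == "[0.5,0.7)"], 1)
  # t1 bin [0.7,1]: g2 (0.75) missed, g3 (0.95) detected -> 1/2
  expect_equal(ev$power$power[ev$power$cell_type == "t1" &
                                ev$power$bin == "[0.7,1]"], 0.5)
  # type I: t2 has 4 null tests, 2 rejected; t1 has 1 null test, 0 rejected
  expect_equal(ev$type1$type1_error[ev$type1$cell_type == "t2"], 0.5)
  expect_equal(ev$type1$type1_error[ev$type1$cell_type == "t1"], 0)
  # saturation / no-rejection edge cases
  sat <- results; sat$p <- 0; sat$q <- 0
  fit_sat <- structure(list(results = sat, cell_types = cts, K = 2L),
                       class = "aei_fit")
  ev_sat <- evaluate_benchmark(fit_sat, truth)
  expect_true(all(ev_sat$overall$power[ev_sat$overall$n > 0] == 1))
  non <- results; non$p <- 1; non$q <- 1
  fit_non <- structure(list(results = non, cell_types = cts, K = 2L),
                       class = "aei_fit")
  ev_non <- evaluate_benchmark(fit_non, truth)
  expect_true(all(ev_non$type1$type1_error[ev_non$type1$n > 0] == 0))
})

test_that("molecular proportions weigh expression by composition", {
  cfg <- small_cfg(seed = 44)
  sim <- simulate_dataset(cfg)
  mp <- molecular_proportions(sim)
  expect_equal(dim(mp), c(60L, 6L))
  manual <- sweep(sweep(sim$reference$signature, 2,
                        sim$reference$cell_sizes, "*"),
                  2, colMeans(sim$proportions), "*")
  expect_equal(mp, manual)
})
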