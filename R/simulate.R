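#' Benchmark simulation configuration
#'
#' Collects the knobs of the pseudo-bulk benchmark generator. Defaults
#' reproduce the study conditions of the published benchmark: 60
#' individuals, 5,000 cells each from six pancreatic-islet cell types with
#' Dirichlet-distributed proportions, 11,300 genes with one transcribed SNP
#' per gene, AEI levels of 0.5 plus a truncated-gamma deviate for
#' AEI-bearing cell types, and a two-condition design with 200 individuals
#' split 1:1 or 7:3 with a differential-AEI shift of 0.1 or 0.2.
#'
#' @param n_individuals Individuals in a one-condition run (default 60).
#' @param n_cells Cells per individual (default 5000).
#' @param n_cell_types Number of cell types (default 6).
#' @param n_snps Genes, one transcribed SNP each (default 11300).
#' @param cell_types Cell-type names; defaults to the six islet types.
#' @param dirichlet_mean Named mean proportions (sum 1).
#' @param dirichlet_concentration Dirichlet concentration (default 3,
#'   matching the wide between-donor composition spread of real pancreatic
#'   islets).
#' @param aei_scenario `"one-cell-type"` (only the major cell type carries
#'   AEI) or `"two-cell-types"` (major and non-major).
#' @param aei_shape,aei_scale,aei_truncation Truncated-gamma parameters of
#'   the AEI deviation above 0.5 (defaults 2, 0.05, truncated at 0.5).
#' @param opposite_fraction In the two-cell-type scenario, fraction of
#'   genes whose two AEI levels point in opposite directions and sum to 1
#'   (default 0.30).
#' @param profile_mean_expr Overall mean per-cell expression per gene
#'   (reads; with `expressed_mean` sets the coverage regime).
#' @param profile_scale Named per-cell-type relative expression scale. The
#'   default for six islet types makes rare stellate cells the
#'   highest-expressing type, reproducing the major-cell-type composition
#'   of the published benchmark (stellate major for roughly a third of
#'   genes, alpha for few).
#' @param expressed_mean Overall mean expressed-cell fraction (default
#'   0.45). Per-type means scale inversely with `profile_scale`, so
#'   high-expressing types express fewer genes per cell and total output
#'   per cell (cell size) is balanced across types.
#' @param profile_meanlog,profile_sdlog Log-normal parameters of the
#'   per-gene per-cell-type mean expression; `profile_meanlog` (scalar or
#'   per-type vector) overrides the `profile_mean_expr`/`profile_scale`
#'   construction when supplied.
#' @param expressed_shape1,expressed_shape2 Beta parameters of the
#'   expressed-cell fractions; `expressed_shape1` (scalar or per-type)
#'   overrides the `expressed_mean` construction when supplied.
#' @param depth_scale Multiplier on the mean-expression profile; tunes the
#'   per-SNP bulk coverage regime (default 1 targets roughly 100-500 reads).
#' @param subject_dispersion Granularity \eqn{s} of the subject-specific
#'   mean-expression draw, \eqn{\mu \sim \mathrm{Poisson}(s\lambda)/s}
#'   (default 2): the subject mean is sampled at the scale of a normalized
#'   multi-cell average, so its between-subject coefficient of variation is
#'   \eqn{1/\sqrt{s\lambda}}; \eqn{s = 1} draws it at the raw per-cell
#'   count scale.
#' @param depth_cv Coefficient of variation of the per-individual
#'   sequencing-depth factor (log-normal, mean 1; default 0.15). This is the variation the
#'   library-size factor \eqn{m_j} of the AEI design absorbs.
#' @param n_total Individuals in a two-condition run (default 200).
#' @param case_ratio Fraction of diseased individuals (0.5 for 1:1, 0.3
#'   for 7:3).
#' @param daei_fraction Fraction of genes with differential AEI
#'   (default 0.5).
#' @param delta_aei Differential-AEI shift added to the diseased group's
#'   AEI (0.1 or 0.2; default 0.1).
#' @param seed Optional integer seed; every random draw of a run flows
#'   from it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 60L, n_cells = 5000L,
                       n_cell_types = 6L, n_snps = 11300L,
                       cell_types = NULL, dirichlet_mean = NULL,
                       dirichlet_concentration = 3,
                       aei_scenario = c("one-cell-type", "two-cell-types"),
                       aei_shape = 2, aei_scale = 0.05,
                       aei_truncation = 0.5, opposite_fraction = 0.30,
                       profile_mean_expr = 0.32, profile_scale = NULL,
                       expressed_mean = 0.45,
                       profile_meanlog = NULL, profile_sdlog = 1.1,
                       profile_gene_sdlog = 0.9,
                       expressed_shape1 = NULL, expressed_shape2 = 12,
                       depth_scale = 1, depth_cv = 0.15,
                       subject_dispersion = 2,
                       n_total = 200L, case_ratio = 0.5,
                       daei_fraction = 0.5, delta_aei = 0.1,
                       seed = NULL) {
  aei_scenario <- match.arg(aei_scenario)
  if (is.null(cell_types)) {
    cell_types <- if (n_cell_types == 6L) {
      c("alpha", "beta", "delta", "ductal", "gamma", "stellate")
    } else {
      sprintf("ct%02d", seq_len(n_cell_types))
    }
  }
  stopifnot(length(cell_types) == n_cell_types, n_cell_types >= 2L,
            n_individuals >= 2L, n_cells >= 1L, n_snps >= 1L)
  if (is.null(dirichlet_mean)) {
    dirichlet_mean <- if (n_cell_types == 6L) {
      c(alpha = 0.38, beta = 0.30, delta = 0.07, ductal = 0.14,
        gamma = 0.07, stellate = 0.04)
    } else {
      stats::setNames(rep(1 / n_cell_types, n_cell_types), cell_types)
    }
  }
  if (is.null(names(dirichlet_mean)))
    names(dirichlet_mean) <- cell_types
  dirichlet_mean <- dirichlet_mean[cell_types]
  if (abs(sum(dirichlet_mean) - 1) > 1e-8)
    stop_ctaei("dirichlet_mean must sum to 1")
  if (aei_truncation > 0.5)
    stop_ctaei("aei_truncation must not exceed 0.5")
  if (is.null(profile_scale)) {
    profile_scale <- if (n_cell_types == 6L) {
      c(alpha = 0.35, beta = 0.8, delta = 0.85, ductal = 1.0,
        gamma = 0.95, stellate = 2.1)
    } else {
      stats::setNames(rep(1, n_cell_types), cell_types)
    }
  }
  if (is.null(names(profile_scale)))
    names(profile_scale) <- cell_types
  profile_scale <- profile_scale[cell_types]
  stopifnot(all(profile_scale > 0), profile_mean_expr > 0,
            expressed_mean > 0, expressed_mean < 1)
  if (is.null(profile_meanlog))
    profile_meanlog <- log(profile_mean_expr * profile_scale) -
      (profile_sdlog^2 + profile_gene_sdlog^2) / 2
  if (is.null(expressed_shape1)) {
    ## per-type expressed-cell fraction mean inversely proportional to the
    ## expression scale, so per-cell total output is balanced across types
    e_k <- pmin(pmax(expressed_mean / profile_scale, 0.02), 0.95)
    expressed_shape1 <- expressed_shape2 * e_k / (1 - e_k)
  }
  stopifnot(dirichlet_concentration > 0, aei_shape > 0, aei_scale > 0,
            aei_truncation > 0, opposite_fraction >= 0,
            opposite_fraction <= 1, depth_scale > 0, depth_cv >= 0,
            subject_dispersion > 0,
            expressed_shape1 > 0, expressed_shape2 > 0,
            n_total >= 2L, case_ratio > 0, case_ratio < 1,
            daei_fraction >= 0, daei_fraction <= 1, delta_aei >= 0)
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_cells = as.integer(n_cells),
    n_cell_types = as.integer(n_cell_types),
    n_snps = as.integer(n_snps),
    cell_types = cell_types, dirichlet_mean = dirichlet_mean,
    dirichlet_concentration = dirichlet_concentration,
    aei_scenario = aei_scenario, aei_shape = aei_shape,
    aei_scale = aei_scale, aei_truncation = aei_truncation,
    opposite_fraction = opposite_fraction,
    profile_mean_expr = profile_mean_expr, profile_scale = profile_scale,
    expressed_mean = expressed_mean,
    profile_meanlog = profile_meanlog, profile_sdlog = profile_sdlog,
    profile_gene_sdlog = profile_gene_sdlog,
    expressed_shape1 = expressed_shape1,
    expressed_shape2 = expressed_shape2,
    depth_scale = depth_scale, depth_cv = depth_cv,
    subject_dispersion = subject_dispersion,
    n_total = as.integer(n_total), case_ratio = case_ratio,
    daei_fraction = daei_fraction, delta_aei = delta_aei,
    seed = seed
  ), class = "sim_config")
}

#' Synthetic per-gene, per-cell-type expression profile
#'
#' A synthetic stand-in for the cell-type-specific mean expression and
#' expressed-cell fractions a practitioner would infer from a real
#' scRNA-seq reference: mean expression per gene and cell type is drawn
#' log-normal and expressed-cell fractions are drawn from a Beta
#' distribution.
#'
#' @param n_genes,n_cell_types Dimensions of the profile.
#' @param meanlog,sdlog Log-normal location (scalar or per type) and
#'   cell-type-specific spread of the mean expression.
#' @param gene_sdlog Spread of the per-gene scale factor shared by all cell
#'   types: most of a gene's expression variation is common to cell types,
#'   as in real transcriptomes, with `sdlog` controlling the residual
#'   type-specific contrast.
#' @param shape1,shape2 Beta parameters of the expressed fractions
#'   (`shape1` may be per type).
#' @param depth_scale Multiplier applied to the means.
#' @param cell_types Optional cell-type names.
#' @param seed Optional integer seed.
#' @return List with `means` and `expressed_fraction`
#'   (genes x cell types), plus `gene_ids` and `cell_types`.
#' @export
sample_reference_profile <- function(n_genes, n_cell_types,
                                     meanlog = log(0.15), sdlog = 0.7,
                                     gene_sdlog = 1.1,
                                     shape1 = 2, shape2 = 4,
                                     depth_scale = 1, cell_types = NULL,
                                     seed = NULL) {
  stopifnot(n_genes >= 1L, n_cell_types >= 1L, sdlog >= 0,
            gene_sdlog >= 0, depth_scale > 0)
  if (is.null(cell_types)) cell_types <- sprintf("ct%02d", seq_len(n_cell_types))
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  if (length(meanlog) == 1L) meanlog <- rep(meanlog, n_cell_types)
  if (length(shape1) == 1L) shape1 <- rep(shape1, n_cell_types)
  stopifnot(length(meanlog) == n_cell_types,
            length(shape1) == n_cell_types)
  with_seed(seed, {
    gene_factor <- stats::rnorm(n_genes, 0, gene_sdlog)
    means <- matrix(depth_scale * exp(
                      rep(meanlog, each = n_genes) +
                        rep(gene_factor, times = n_cell_types) +
                        stats::rnorm(n_genes * n_cell_types, 0, sdlog)),
                    nrow = n_genes,
                    dimnames = list(gene_ids, cell_types))
    fractions <- matrix(stats::rbeta(n_genes * n_cell_types,
                                     rep(shape1, each = n_genes), shape2),
                        nrow = n_genes,
                        dimnames = list(gene_ids, cell_types))
    list(means = means, expressed_fraction = fractions,
         gene_ids = gene_ids, cell_types = cell_types)
  })
}

## truncated Gamma on (0, trunc] by inverse-CDF; deterministic under seed
rtrunc_gamma <- function(n, shape, scale, trunc) {
  pmax_p <- stats::pgamma(trunc, shape = shape, scale = scale)
  stats::qgamma(stats::runif(n) * pmax_p, shape = shape, scale = scale)
}

#' Draw per-gene, per-cell-type AEI levels
#'
#' AEI (the reference-allele fraction of allelic reads) is 0.5 for cell
#' types without allelic imbalance. For AEI-bearing cell types it is 0.5
#' plus a truncated-gamma deviate, so most genes carry small to moderate
#' imbalance. In the two-cell-type scenario a fraction of genes has the
#' non-major cell type imbalanced in the opposite direction, with the two
#' AEI levels summing to 1; the remaining genes have both levels above 0.5.
#'
#' @param n_genes Number of genes.
#' @param scenario `"one-cell-type"` or `"two-cell-types"`.
#' @param shape,scale,truncation Truncated-gamma parameters (truncation
#'   must not exceed 0.5, keeping AEI in (0.5, 1)).
#' @param opposite_fraction Fraction of genes with opposite directions
#'   (two-cell-type scenario only).
#' @param major,nonmajor Integer vectors giving the major / non-major cell
#'   type column per gene.
#' @param cell_types Cell-type names.
#' @param seed Optional integer seed.
#' @return List with `aei` (genes x cell types, 0.5 where no imbalance)
#'   and `opposite` (logical per gene; `NA` for the one-cell-type
#'   scenario).
#' @export
sample_aei_levels <- function(n_genes,
                              scenario = c("one-cell-type",
                                           "two-cell-types"),
                              shape = 2, scale = 0.05, truncation = 0.5,
                              opposite_fraction = 0.30, major, nonmajor,
                              cell_types, seed = NULL) {
  scenario <- match.arg(scenario)
  if (truncation > 0.5) stop_ctaei("truncation must not exceed 0.5")
  stopifnot(length(major) == n_genes, length(nonmajor) == n_genes)
  with_seed(seed, {
    aei <- matrix(0.5, nrow = n_genes, ncol = length(cell_types),
                  dimnames = list(names(major) %||%
                                    sprintf("gene_%05d", seq_len(n_genes)),
                                  cell_types))
    gi <- seq_len(n_genes)
    aei[cbind(gi, major)] <-
      0.5 + rtrunc_gamma(n_genes, shape, scale, truncation)
    opposite <- rep(NA, n_genes)
    if (scenario == "two-cell-types") {
      opposite <- rep(FALSE, n_genes)
      n_opp <- round(opposite_fraction * n_genes)
      if (n_opp > 0L) opposite[sample.int(n_genes, n_opp)] <- TRUE
      same <- !opposite
      aei[cbind(gi[same], nonmajor[same])] <-
        0.5 + rtrunc_gamma(sum(same), shape, scale, truncation)
      aei[cbind(gi[opposite], nonmajor[opposite])] <-
        1 - aei[cbind(gi[opposite], major[opposite])]
    }
    list(aei = aei, opposite = opposite)
  })
}

## Deterministic cell-count allocation: largest-remainder rounding of
## n_cells * p so the counts sum exactly to n_cells.
allocate_cells <- function(p, n_cells) {
  raw <- n_cells * p
  base <- floor(raw)
  short <- n_cells - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## One layer of the generative scheme for a block of individuals sharing an
## AEI matrix. Exact aggregation of the per-cell description: the number of
## expressed cells of type k is Binomial(n_k, f_gk); the sum of their iid
## Poisson(mu) totals is Poisson(n_expr * mu); binomial allele splitting
## commutes with the sum. `depth` is the per-individual sequencing-depth
## multiplier applied to the subject-mean rate; `subject_scale` is the
## granularity of the subject-mean draw: mu ~ Poisson(s * rate) / s, so the
## between-subject coefficient of variation is 1 / sqrt(s * rate).
simulate_counts_block <- function(cells, means, fractions, aei, depth,
                                  subject_scale = 2) {
  n_ind <- nrow(cells)
  n_genes <- nrow(means)
  ref <- tot <- matrix(0L, nrow = n_ind, ncol = n_genes)
  for (k in seq_len(ncol(cells))) {
    n_draw <- n_ind * n_genes
    n_expr <- stats::rbinom(n_draw, size = rep(cells[, k], times = n_genes),
                            prob = rep(fractions[, k], each = n_ind))
    mu <- stats::rpois(n_draw, lambda = subject_scale *
                                 rep(depth, times = n_genes) *
                                 rep(means[, k], each = n_ind)) /
      subject_scale
    tot_k <- stats::rpois(n_draw, lambda = n_expr * mu)
    ref_k <- stats::rbinom(n_draw, size = tot_k,
                           prob = rep(aei[, k], each = n_ind))
    tot <- tot + matrix(tot_k, nrow = n_ind)
    ref <- ref + matrix(ref_k, nrow = n_ind)
  }
  list(ref = ref, tot = tot)
}

#' Simulate a one-condition pseudo-bulk benchmark dataset
#'
#' Generates allele-specific pseudo-bulk counts per the benchmark scheme:
#' per-individual cell-type proportions are Dirichlet; for each gene and
#' cell type a subject-specific mean expression is drawn Poisson around the
#' reference profile mean; each expressed cell's total read count is
#' Poisson around that mean; totals are split into reference/alternative
#' allele counts by a Binomial with probability equal to the cell type's
#' AEI level; pseudo-bulk counts sum across cells. Genes with zero bulk
#' coverage are retained (downstream filtering removes them).
#'
#' @param config A [sim_config()].
#' @return Object of class `aei_sim`: list with `counts` (allele-count
#'   table), `bulk` (genes x samples total counts), `proportions` (true
#'   per-individual proportions), `reference` (synthetic
#'   [sc_reference][build_reference]), `truth` (class `sim_truth`:
#'   per-gene AEI matrix, major/non-major labels, opposite-direction
#'   flags), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed,
            simulate_one_condition(config, config$n_individuals))
}

simulate_one_condition <- function(cfg, n_ind) {
  ## sample profile + proportions + counts in one stream
  prof <- sample_reference_profile(
    cfg$n_snps, cfg$n_cell_types, meanlog = cfg$profile_meanlog,
    sdlog = cfg$profile_sdlog, gene_sdlog = cfg$profile_gene_sdlog,
    shape1 = cfg$expressed_shape1,
    shape2 = cfg$expressed_shape2, depth_scale = cfg$depth_scale,
    cell_types = cfg$cell_types)
  mn <- select_major_nonmajor(prof$means)
  lev <- sample_aei_levels(cfg$n_snps, cfg$aei_scenario, cfg$aei_shape,
                           cfg$aei_scale, cfg$aei_truncation,
                           cfg$opposite_fraction, mn$major, mn$nonmajor,
                           cfg$cell_types)
  core <- simulate_core_with_profile(cfg, n_ind, list(lev$aei),
                                     rep(1L, n_ind), prof)
  truth <- structure(list(
    aei = lev$aei, major = cfg$cell_types[mn$major],
    nonmajor = cfg$cell_types[mn$nonmajor], opposite = lev$opposite,
    proportions = core$proportions
  ), class = "sim_truth")
  structure(list(counts = core$counts, bulk = core$bulk,
                 proportions = core$proportions,
                 reference = core$reference, truth = truth,
                 condition = NULL, config = cfg),
            class = "aei_sim")
}

## Major cell type: highest mean expression; non-major: the cell type with
## median mean expression (upper median for an even number of types); ties
## broken by cell-type (column) order.
select_major_nonmajor <- function(means) {
  K <- ncol(means)
  med_pos <- floor(K / 2) + 1L
  major <- max.col(means, ties.method = "first")
  nonmajor <- apply(means, 1L, function(x) order(x)[med_pos])
  if (any(major == nonmajor))
    nonmajor[major == nonmajor] <-
      apply(means[major == nonmajor, , drop = FALSE], 1L,
            function(x) order(x)[max(1L, floor(ncol(means) / 2))])
  list(major = major, nonmajor = nonmajor)
}

simulate_core_with_profile <- function(cfg, n_ind, aei_list, cond_index,
                                       prof) {
  ids <- sprintf("ind_%03d", seq_len(n_ind))
  alpha <- cfg$dirichlet_concentration * cfg$dirichlet_mean
  P <- matrix(stats::rgamma(n_ind * cfg$n_cell_types,
                            shape = rep(alpha, each = n_ind)),
              nrow = n_ind, dimnames = list(ids, cfg$cell_types))
  P <- P / rowSums(P)
  cells <- t(apply(P, 1L, allocate_cells, n_cells = cfg$n_cells))
  colnames(cells) <- cfg$cell_types
  ## per-individual sequencing depth factor (library-size variation)
  depth <- if (cfg$depth_cv > 0) {
    sdl <- sqrt(log(1 + cfg$depth_cv^2))
    stats::rlnorm(n_ind, meanlog = -sdl^2 / 2, sdlog = sdl)
  } else rep(1, n_ind)

  ref <- tot <- matrix(0L, nrow = n_ind, ncol = cfg$n_snps)
  for (ci in seq_along(aei_list)) {
    block <- which(cond_index == ci)
    if (!length(block)) next
    counts <- simulate_counts_block(cells[block, , drop = FALSE],
                                    prof$means, prof$expressed_fraction,
                                    aei_list[[ci]], depth[block],
                                    cfg$subject_dispersion)
    ref[block, ] <- counts$ref
    tot[block, ] <- counts$tot
  }

  snp_ids <- sub("^gene_", "snp_", prof$gene_ids)
  counts_tab <- data.frame(
    snp_id = rep(snp_ids, each = n_ind),
    gene_id = rep(prof$gene_ids, each = n_ind),
    sample_id = rep(ids, times = cfg$n_snps),
    ref_count = as.integer(ref),
    alt_count = as.integer(tot - ref),
    stringsAsFactors = FALSE
  )
  bulk <- t(tot)
  dimnames(bulk) <- list(prof$gene_ids, ids)
  storage.mode(bulk) <- "integer"

  signature <- sweep(prof$means, 2L, colSums(prof$means), "/")
  reference <- new_sc_reference(
    signature,
    stats::setNames(colSums(prof$means * prof$expressed_fraction),
                    cfg$cell_types),
    prof$expressed_fraction)

  list(counts = counts_tab, bulk = bulk, proportions = P,
       reference = reference, snp_ids = snp_ids, cells = cells)
}

#' Simulate a two-condition (e.g. healthy vs diseased) benchmark dataset
#'
#' As [simulate_dataset()], with individuals split into two conditions.
#' Only the major cell type carries AEI; for a configurable fraction of
#' genes the diseased group's AEI level is higher than the healthy group's
#' by `delta_aei`. Healthy AEI levels whose shifted value would reach 1
#' are resampled so both levels stay in (0.5, 1).
#'
#' @param config A [sim_config()]; uses the two-condition fields
#'   (`n_total`, `case_ratio`, `daei_fraction`, `delta_aei`).
#' @return Object of class `aei_sim` whose `condition` element is a named
#'   0/1 vector (1 = diseased) and whose `truth` carries `aei_healthy`,
#'   `aei_diseased`, the per-gene `daei` flag and `delta`.
#' @export
simulate_two_condition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_ind <- cfg$n_total
  with_seed(cfg$seed, {
    prof <- sample_reference_profile(
      cfg$n_snps, cfg$n_cell_types, meanlog = cfg$profile_meanlog,
      sdlog = cfg$profile_sdlog, gene_sdlog = cfg$profile_gene_sdlog,
      shape1 = cfg$expressed_shape1,
      shape2 = cfg$expressed_shape2, depth_scale = cfg$depth_scale,
      cell_types = cfg$cell_types)
    mn <- select_major_nonmajor(prof$means)
    lev <- sample_aei_levels(cfg$n_snps, "one-cell-type", cfg$aei_shape,
                             cfg$aei_scale, cfg$aei_truncation,
                             cfg$opposite_fraction, mn$major, mn$nonmajor,
                             cfg$cell_types)
    aei_healthy <- lev$aei
    gi <- seq_len(cfg$n_snps)
    daei <- rep(FALSE, cfg$n_snps)
    n_daei <- round(cfg$daei_fraction * cfg$n_snps)
    if (n_daei > 0L) daei[sample.int(cfg$n_snps, n_daei)] <- TRUE
    if (cfg$delta_aei > 0) {
      ## resample healthy levels that would push the diseased level to 1
      bad <- daei &
        aei_healthy[cbind(gi, mn$major)] + cfg$delta_aei >= 1
      while (any(bad)) {
        aei_healthy[cbind(gi[bad], mn$major[bad])] <-
          0.5 + rtrunc_gamma(sum(bad), cfg$aei_shape, cfg$aei_scale,
                             cfg$aei_truncation)
        bad <- daei &
          aei_healthy[cbind(gi, mn$major)] + cfg$delta_aei >= 1
      }
    }
    aei_diseased <- aei_healthy
    aei_diseased[cbind(gi[daei], mn$major[daei])] <-
      aei_healthy[cbind(gi[daei], mn$major[daei])] + cfg$delta_aei

    n_cases <- round(n_ind * cfg$case_ratio)
    cond <- c(rep(0L, n_ind - n_cases), rep(1L, n_cases))
    core <- simulate_core_with_profile(cfg, n_ind,
                                       list(aei_healthy, aei_diseased),
                                       cond + 1L, prof)
    names(cond) <- rownames(core$proportions)
    truth <- structure(list(
      aei = aei_healthy, aei_healthy = aei_healthy,
      aei_diseased = aei_diseased, daei = daei,
      delta = aei_diseased - aei_healthy,
      major = cfg$cell_types[mn$major],
      nonmajor = cfg$cell_types[mn$nonmajor],
      opposite = lev$opposite, proportions = core$proportions
    ), class = "sim_truth")
    structure(list(counts = core$counts, bulk = core$bulk,
                   proportions = core$proportions,
                   reference = core$reference, truth = truth,
                   condition = cond, config = cfg),
              class = "aei_sim")
  })
}

#' @export
print.aei_sim <- function(x, ...) {
  cat("Simulated pseudo-bulk benchmark dataset\n")
  cat("  individuals:", nrow(x$proportions),
      " genes/SNPs:", nrow(x$bulk),
      " cell types:", ncol(x$proportions), "\n")
  cat("  mean per-SNP bulk coverage:", round(mean(x$bulk), 1), "reads\n")
  if (!is.null(x$condition))
    cat("  conditions: healthy =", sum(x$condition == 0),
        ", diseased =", sum(x$condition == 1), "\n")
  invisible(x)
}

#' Mean molecular proportions of a simulated dataset
#'
#' The molecular proportion of a cell type for a gene is its mean
#' expression multiplied by the cell-type proportion: the share of bulk
#' molecules attributable to the cell type. Useful as a diagnostic of
#' which cell types drive detection power.
#'
#' @param dataset An `aei_sim` object.
#' @return Genes-by-cell-types matrix of mean molecular proportions
#'   (averaged over individuals).
#' @export
molecular_proportions <- function(dataset) {
  stopifnot(inherits(dataset, "aei_sim"))
  ## rescale the signature by cell size to recover mean expression per
  ## cell, then weight by the mean proportions
  expr <- sweep(dataset$reference$signature, 2L,
                dataset$reference$cell_sizes, "*")
  sweep(expr, 2L, colMeans(dataset$proportions), "*")
}
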