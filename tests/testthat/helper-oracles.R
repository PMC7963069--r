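# Independent oracles used across the suite. These deliberately avoid the
# package's own fitting code paths: OLS via explicit normal equations,
# logistic regression via a hand-rolled IRLS loop, LD misalignment via
# diplotype enumeration.

# OLS through solve(t(X) %*% X): estimates, SEs, t, two-sided p
ols_oracle <- function(y, X) {
  xtx <- solve(t(X) %*% X)
  beta <- drop(xtx %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(xtx) * s2)
  tstat <- beta / se
  list(coef = beta, se = se, t = tstat, df = df,
       p = 2 * pt(-abs(tstat), df), sigma2 = s2)
}

# binomial-logit IRLS with Wald statistics
irls_logit_oracle <- function(ref, alt, X, tol = 1e-12, maxit = 100L) {
  n <- ref + alt
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- n * mu * (1 - mu)
    z <- eta + (ref - n * mu) / w
    xtwx <- t(X) %*% (X * w)
    beta_new <- drop(solve(xtwx, t(X) %*% (w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- n * mu * (1 - mu)
  se <- sqrt(diag(solve(t(X) %*% (X * w))))
  list(coef = beta, se = se, z = beta / se,
       p = 2 * pnorm(-abs(beta / se)))
}

# exact misalignment fraction by enumerating all 10 diplotypes under HWE
ld_enumeration_oracle <- function(maf_t, maf_r, r2) {
  p1 <- maf_t; p2 <- 1 - maf_t
  q1 <- maf_r; q2 <- 1 - maf_r
  D <- sqrt(r2 * p1 * p2 * q1 * q2)
  h <- c(AB = p1 * q1 + D, Ab = p1 * q2 - D,
         aB = p2 * q1 - D, ab = p2 * q2 + D)
  stopifnot(all(h >= -1e-12))
  h <- pmax(h, 0)
  tsnp_allele <- c(AB = "A", Ab = "A", aB = "a", ab = "a")
  rsnp_allele <- c(AB = "B", Ab = "b", aB = "B", ab = "b")
  p_het_t <- 0
  p_repulsion <- 0
  for (i in names(h)) for (j in names(h)) {
    pr <- h[[i]] * h[[j]]
    het_t <- tsnp_allele[[i]] != tsnp_allele[[j]]
    het_r <- rsnp_allele[[i]] != rsnp_allele[[j]]
    if (het_t) p_het_t <- p_het_t + pr
    # repulsion double het: haplotypes are Ab/aB
    if (het_t && het_r && i %in% c("Ab", "aB") && j %in% c("Ab", "aB"))
      p_repulsion <- p_repulsion + pr
  }
  p_repulsion / p_het_t
}

# tiny well-formed allele-count table
make_counts <- function(snp = "rs1", gene = "g1", samples, ref, alt) {
  data.frame(snp_id = snp, gene_id = gene, sample_id = samples,
             ref_count = ref, alt_count = alt, stringsAsFactors = FALSE)
}

# allele-count table for one SNP constructed from a numeric y = ref - alt
# (total fixed high enough that ref, alt stay non-negative)
counts_from_y <- function(y, samples, snp = "rs1", gene = "g1",
                          total = NULL) {
  y <- round(y)
  if (is.null(total)) total <- max(200, 2 * max(abs(y)) + 10)
  total_i <- total + (total + y) %% 2   # parity so (total + y)/2 is integral
  ref <- (total_i + y) / 2
  alt <- total_i - ref
  make_counts(snp, gene, samples, as.integer(ref), as.integer(alt))
}

# small random design for K cell types over n samples
random_design <- function(n, K, seed) {
  withr::with_seed(seed, {
    P <- matrix(rgamma(n * K, shape = 2), nrow = n)
    P <- P / rowSums(P)
    m <- exp(rnorm(n, 0, 0.2))
    D <- P * m
    dimnames(D) <- list(sprintf("s%02d", seq_len(n)),
                        sprintf("ct%d", seq_len(K)))
    D
  })
}
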