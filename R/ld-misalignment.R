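#' Fraction of individuals misaligned under incomplete LD
#'
#' Cross-individual AEI analysis aligns allelic read counts by the alleles
#' of the transcribed SNP (tSNP), assuming it tags the unobserved
#' cis-regulatory SNP perfectly. Under incomplete linkage disequilibrium a
#' tSNP-heterozygous individual can carry the two variants in repulsion
#' phase, flipping the sign of its allelic difference. This function
#' computes, analytically under Hardy-Weinberg random mating, the
#' proportion of tSNP-heterozygous individuals that are repulsion-phase
#' double heterozygotes — the misaligned fraction.
#'
#' Haplotype frequencies use the coupling-phase orientation
#' \eqn{D = +\sqrt{r^2 \, p(1-p) q(1-q)}} (the tSNP reference allele rides
#' with the expression-increasing regulatory allele). With tSNP allele
#' frequencies \eqn{p_1, p_2} and regulatory-SNP frequencies
#' \eqn{q_1, q_2}, the repulsion haplotypes have frequencies
#' \eqn{h_{12} = p_1 q_2 - D} and \eqn{h_{21} = p_2 q_1 - D}, and the
#' misaligned fraction is \eqn{h_{12} h_{21} / (p_1 p_2)}. tSNP
#' heterozygotes homozygous at the regulatory SNP contribute no allelic
#' imbalance (their signal is diluted, not sign-flipped) and are not
#' counted as misaligned; [misalignment_grid()] reports that no-signal
#' fraction separately.
#'
#' @param maf_t Minor allele frequency of the transcribed SNP, in
#'   `(0, 0.5]`.
#' @param maf_r Minor allele frequency of the regulatory SNP, in
#'   `(0, 0.5]`.
#' @param r2 Squared LD correlation between the two SNPs, in `[0, 1]`.
#'   Must be admissible for the given frequencies (all four haplotype
#'   frequencies non-negative).
#' @return Misaligned fraction in `[0, 1]`; exactly 0 at `r2 = 1` with
#'   equal MAFs. Vectorized over its arguments.
#' @export
misalignment_proportion <- function(maf_t, maf_r, r2) {
  n <- max(length(maf_t), length(maf_r), length(r2))
  maf_t <- rep_len(maf_t, n); maf_r <- rep_len(maf_r, n)
  r2 <- rep_len(r2, n)
  if (any(maf_t <= 0 | maf_t > 0.5) || any(maf_r <= 0 | maf_r > 0.5))
    stop_ctaei("minor allele frequencies must lie in (0, 0.5]")
  if (any(r2 < 0 | r2 > 1)) stop_ctaei("r2 must lie in [0, 1]")
  p1 <- maf_t; p2 <- 1 - maf_t
  q1 <- maf_r; q2 <- 1 - maf_r
  D <- sqrt(r2 * p1 * p2 * q1 * q2)
  d_max <- pmin(p1 * q2, p2 * q1)
  bad <- D > d_max + 1e-12
  if (any(bad))
    stop_ctaei("inadmissible (maf, r2): D = ", signif(D[bad][1L], 4),
               " exceeds the haplotype bound min(p1*q2, p2*q1) = ",
               signif(d_max[bad][1L], 4))
  h12 <- pmax(p1 * q2 - D, 0)
  h21 <- pmax(p2 * q1 - D, 0)
  h12 * h21 / (p1 * p2)
}

#' Misalignment and no-signal fractions over a MAF by r2 grid
#'
#' Evaluates [misalignment_proportion()] on the cross product of the
#' supplied MAF and r2 values, reporting for each admissible scenario the
#' misaligned fraction (repulsion-phase double heterozygotes among tSNP
#' heterozygotes) and the no-signal fraction (tSNP heterozygotes
#' homozygous at the regulatory SNP). Inadmissible combinations are
#' dropped.
#'
#' @param maf_t,maf_r Vectors of minor allele frequencies; by default the
#'   regulatory-SNP MAFs mirror the tSNP MAFs elementwise after crossing.
#' @param r2 Vector of squared LD correlations.
#' @return `data.frame` with columns `maf_t`, `maf_r`, `r2`, `misaligned`,
#'   `no_signal`.
#' @export
misalignment_grid <- function(maf_t, maf_r = maf_t, r2) {
  grid <- expand.grid(maf = seq_along(maf_t), r2 = r2,
                      KEEP.OUT.ATTRS = FALSE)
  if (length(maf_r) != length(maf_t))
    stop_ctaei("maf_r must align elementwise with maf_t")
  p1 <- maf_t[grid$maf]; q1 <- maf_r[grid$maf]
  p2 <- 1 - p1; q2 <- 1 - q1
  D <- sqrt(grid$r2 * p1 * p2 * q1 * q2)
  ok <- D <= pmin(p1 * q2, p2 * q1) + 1e-12
  p1 <- p1[ok]; p2 <- p2[ok]; q1 <- q1[ok]; q2 <- q2[ok]
  r2v <- grid$r2[ok]
  mis <- misalignment_proportion(p1, q1, r2v)
  D <- sqrt(r2v * p1 * p2 * q1 * q2)
  h11 <- p1 * q1 + D; h12 <- pmax(p1 * q2 - D, 0)
  h21 <- pmax(p2 * q1 - D, 0); h22 <- p2 * q2 + D
  ## among tSNP hets (prob 2*p1*p2): double het = 2*(h11 h22 + h12 h21)
  no_signal <- pmax(1 - (h11 * h22 + h12 * h21) / (p1 * p2), 0)
  data.frame(maf_t = p1, maf_r = q1, r2 = r2v, misaligned = mis,
             no_signal = no_signal)
}
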