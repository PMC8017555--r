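#' Construct a genotype panel object
#'
#' @param dosage n x m matrix of allele dosages in {0, 1, 2} (individuals
#'   by SNPs).
#' @param pos SNP positions in bp, non-decreasing.
#' @param variant_id optional SNP ids (defaults to snp1..snpm).
#' @param chrom chromosome label (single value).
#' @return object of class \code{genotype_panel} with dosage, positions,
#'   ids and per-SNP MAF; monomorphic SNPs are disallowed.
#' @export
genotype_panel <- function(dosage, pos, variant_id = NULL, chrom = "chr1") {
  stop_if(length(pos) != ncol(dosage), "pos length must match SNP count")
  stop_if(is.unsorted(pos), "SNP positions must be non-decreasing")
  if (is.null(variant_id)) variant_id <- paste0("snp", seq_len(ncol(dosage)))
  freq <- colMeans(dosage) / 2
  stop_if(any(freq == 0 | freq == 1),
          "panel contains monomorphic SNPs; filter before constructing")
  structure(list(dosage = dosage, pos = pos, variant_id = variant_id,
                 chrom = chrom, maf = pmin(freq, 1 - freq)),
            class = "genotype_panel")
}

#' Annotation-stratified LD scores
#'
#' For each SNP j and category C, the LD score is
#' \eqn{\ell_j(C) = \sum_k a_k(C) \, r^2_{adj}(j,k)} over SNPs k within
#' \code{window_bp} of j (including j itself), where
#' \eqn{r^2_{adj} = r^2 - (1 - r^2)/(n - 2)} is the small-sample-adjusted
#' squared dosage correlation.
#'
#' @param panel \code{genotype_panel}.
#' @param annotations m x C binary matrix with named columns; must include
#'   a base category of all ones.
#' @param window_bp LD window half-width in bp (default 1 Mb).
#' @return m x C matrix of LD scores (class \code{matrix}), with the SNP
#'   positions attached as attribute \code{pos}.
#' @export
compute_ld_scores <- function(panel, annotations, window_bp = 1e6) {
  X <- panel$dosage
  n <- nrow(X)
  m <- ncol(X)
  stop_if(n <= 3, "LD estimation needs more than 3 individuals")
  stop_if(window_bp < 0, "window must be >= 0 bp")
  annotations <- as.matrix(annotations)
  stop_if(nrow(annotations) != m, "annotation rows must match SNP count")
  stop_if(!any(colSums(annotations) == m),
          "annotations must include a base category covering all SNPs")
  sds <- apply(X, 2, stats::sd)
  stop_if(any(sds == 0), "constant dosage column(s); filter before scoring")
  Xs <- scale(X)
  pos <- panel$pos
  lo <- findInterval(pos - window_bp, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos + window_bp, pos)
  out <- matrix(0, m, ncol(annotations),
                dimnames = list(panel$variant_id, colnames(annotations)))
  for (j in seq_len(m)) {
    idx <- lo[j]:hi[j]
    r <- crossprod(Xs[, j], Xs[, idx, drop = FALSE])[1, ] / (n - 1)
    r2 <- r^2
    r2_adj <- r2 - (1 - r2) / (n - 2)
    out[j, ] <- crossprod(annotations[idx, , drop = FALSE], r2_adj)
  }
  attr(out, "pos") <- pos
  out
}

#' Stratified LD-score regression core
#'
#' Regresses per-SNP GWAS chi-square statistics on annotation-stratified LD
#' scores (weighted least squares with an intercept; predictors scaled as
#' \eqn{N \ell_j(C) / M}), converts coefficients into per-category
#' heritability, and reports the enrichment of each category:
#' \deqn{enrichment_C = (h^2_C / h^2) / (M_C / M).}
#' Standard errors come from a contiguous block jackknife over SNPs.
#'
#' @param chisq per-SNP chi-square statistics (length m).
#' @param ldscores m x C LD-score matrix from
#'   \code{\link{compute_ld_scores}}.
#' @param annotations m x C binary membership matrix (same columns).
#' @param N GWAS sample size.
#' @param weights optional regression weights. By default a two-step
#'   scheme is used: a first pass weighted by the inverse base LD score
#'   (floored at 1, the usual correction for LD-induced overcounting)
#'   yields a method-of-moments estimate of the mean per-SNP signal, and
#'   the final fit additionally downweights high-LD SNPs for the
#'   heteroskedasticity of chi-square statistics,
#'   \eqn{w_j = 1 / [\max(\ell_j, 1)\,(1 + N \bar{h}^2 \ell_j)^2]}.
#' @param n_blocks jackknife blocks (default 20).
#' @return list of class \code{sldsc_result}: \code{tau} (per-SNP
#'   heritability coefficients), \code{intercept}, \code{h2} per category,
#'   \code{M} per category, \code{enrichment}, \code{enrichment_se}.
#' @export
fit_sldsc <- function(chisq, ldscores, annotations, N,
                      weights = NULL, n_blocks = 20) {
  annotations <- as.matrix(annotations)
  ldscores <- as.matrix(ldscores)
  m <- length(chisq)
  stop_if(nrow(ldscores) != m || nrow(annotations) != m,
          "chisq, ldscores and annotations must agree on SNP count")
  stop_if(N <= 0, "N must be positive")
  M_c <- colSums(annotations)
  base <- which(M_c == m)[1]
  stop_if(is.na(base), "no base category covering all SNPs")
  M <- M_c[base]
  lb <- ldscores[, base]
  if (is.null(weights)) {
    # two-step: overcounting weights, then add chi-square heteroskedasticity
    hbar <- max((stats::weighted.mean(chisq, 1 / pmax(lb, 1)) - 1) /
                  (N * stats::weighted.mean(lb, 1 / pmax(lb, 1))), 0)
    weights <- 1 / (pmax(lb, 1) * (1 + N * hbar * lb)^2)
  }

  X <- cbind(intercept = 1, N * ldscores / M)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("singular design; collinear categories: %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }

  fit_once <- function(keep) {
    f <- stats::lm.wfit(X[keep, , drop = FALSE], chisq[keep], weights[keep])
    theta <- f$coefficients
    tau <- theta[-1] / M          # per-SNP heritability coefficients
    per_snp_h2 <- as.numeric(annotations %*% tau)
    h2_c <- as.numeric(crossprod(annotations, per_snp_h2))
    h2 <- h2_c[base]
    enr <- if (h2 == 0) ifelse(seq_along(h2_c) == base, 1, NA_real_)
           else (h2_c / h2) / (M_c / M)
    list(tau = tau, intercept = theta[1], h2_c = h2_c, enr = enr)
  }

  full <- fit_once(rep(TRUE, m))
  blocks <- cut(seq_len(m), breaks = min(n_blocks, m), labels = FALSE)
  jk <- vapply(unique(blocks), function(b) fit_once(blocks != b)$enr,
               numeric(ncol(annotations)))
  jk <- matrix(jk, nrow = ncol(annotations))
  B <- ncol(jk)
  jk_mean <- rowMeans(jk)
  enr_se <- sqrt((B - 1) / B * rowSums((jk - jk_mean)^2))

  structure(list(
    tau = stats::setNames(full$tau, colnames(annotations)),
    intercept = unname(full$intercept),
    h2 = stats::setNames(full$h2_c, colnames(annotations)),
    M = stats::setNames(M_c, colnames(annotations)),
    enrichment = stats::setNames(full$enr, colnames(annotations)),
    enrichment_se = stats::setNames(enr_se, colnames(annotations)),
    n_blocks = B
  ), class = "sldsc_result")
}

#' @export
print.sldsc_result <- function(x, ...) {
  cat(sprintf("SLDSC: intercept %.3f, %d categories\n",
              x$intercept, length(x$tau)))
  for (c in names(x$enrichment)) {
    cat(sprintf("  %s: enrichment %.2f (SE %.2f), M = %d\n",
                c, x$enrichment[c], x$enrichment_se[c], x$M[c]))
  }
  invisible(x)
}
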