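#' Single-sample GSEA enrichment score
#'
#' Ranks one sample's genes by expression (decreasing; ties broken by gene
#' order) and accumulates the weighted running sum
#' \deqn{ES = \sum_i \left[ P_{hit}(i) - P_{miss}(i) \right],}
#' where the hit increments are \eqn{|r_i|^\alpha} for the rank statistic
#' r (n for the most expressed gene down to 1) and misses increment
#' uniformly. Because only ranks enter, the score is invariant under any
#' strictly increasing transform of the sample's values.
#'
#' @param values named numeric vector of one sample's expression.
#' @param gene_set character vector of gene names; must be a non-empty
#'   proper subset of the expressed genes.
#' @param alpha rank weight exponent (default 0.25, the conventional
#'   ssGSEA setting).
#' @return the (unnormalized) enrichment score.
#' @export
ssgsea <- function(values, gene_set, alpha = 0.25) {
  n <- length(values)
  stop_if(is.null(names(values)), "expression values must be named by gene")
  stop_if(length(gene_set) == 0L, "gene set is empty")
  stop_if(!all(gene_set %in% names(values)),
          "gene set contains genes absent from the sample")
  in_set <- names(values) %in% gene_set
  stop_if(all(in_set), "gene set equals the full gene universe")

  ord <- order(-values)          # decreasing expression, stable for ties
  hit <- in_set[ord]
  r_stat <- n:1                  # rank statistic: n = most expressed
  w <- abs(r_stat)^alpha
  hit_w <- ifelse(hit, w, 0)
  p_hit <- cumsum(hit_w) / sum(hit_w)
  p_miss <- cumsum(!hit) / (n - sum(in_set))
  sum(p_hit - p_miss)
}

#' ssGSEA scores for an expression matrix
#'
#' Per-sample enrichment scores for one gene set, optionally normalized by
#' the range (max - min) of raw scores across samples, as is conventional
#' when comparing groups of samples.
#'
#' @param expr genes x samples numeric matrix with rownames.
#' @param gene_set character vector of gene names.
#' @param alpha rank weight exponent (default 0.25).
#' @param normalize divide by the across-sample score range (default TRUE).
#' @return named numeric vector of scores, one per sample.
#' @export
ssgsea_scores <- function(expr, gene_set, alpha = 0.25, normalize = TRUE) {
  es <- apply(expr, 2, function(col) {
    names(col) <- rownames(expr)
    ssgsea(col, gene_set, alpha)
  })
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  es
}

#' Differential expression between two groups (Welch t-test)
#'
#' Per-gene Welch t statistics between tumor and normal samples on the
#' supplied (typically log-scale) expression matrix, with two-sided
#' p-values and Benjamini-Hochberg adjustment. Genes with zero variance in
#' both groups have an undefined statistic and are flagged rather than
#' silently dropped.
#'
#' @param expr genes x samples numeric matrix.
#' @param labels factor/character of length ncol(expr) with two levels;
#'   the first level encountered is the reference (e.g. "normal").
#' @param sig_level BH q-value threshold for the \code{significant} flag
#'   (default 0.05).
#' @return data.frame with \code{gene_id}, group means, \code{t},
#'   \code{df}, \code{p_value}, \code{q_value}, \code{significant},
#'   \code{undefined}.
#' @export
diff_expression <- function(expr, labels, sig_level = 0.05) {
  labels <- as.factor(labels)
  stop_if(nlevels(labels) != 2L, "labels must have exactly two levels")
  stop_if(min(table(labels)) < 2L, "need at least 2 samples per group")
  g1 <- labels == levels(labels)[1]
  g2 <- labels == levels(labels)[2]
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, g2, drop = FALSE])
  v1 <- apply(expr[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(expr[, g2, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  undefined <- se2 == 0
  t <- ifelse(undefined, NA_real_, (m2 - m1) / sqrt(se2))
  df <- ifelse(undefined, NA_real_,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  if (any(undefined)) {
    warning(sprintf("%d gene(s) with zero variance in both groups", sum(undefined)))
  }
  data.frame(
    gene_id = if (is.null(rownames(expr))) paste0("gene", seq_len(nrow(expr)))
              else rownames(expr),
    mean_ref = m1, mean_alt = m2, t = t, df = df,
    p_value = p, q_value = q,
    significant = !is.na(q) & q < sig_level,
    undefined = undefined,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
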