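#' Approximate Bayes factor for a marginal association
#'
#' Computes the Wakefield-style approximate Bayes factor in favour of
#' association from a marginal effect estimate and its standard error,
#' under a normal prior N(0, W) on the effect:
#' \deqn{ABF = \sqrt{V/(V+W)} \exp\{z^2 W / (2 (V+W))\}, \quad V = se^2,
#'   \; z = \beta / se.}
#' With \code{W = 0} the prior puts all mass on zero effect and the Bayes
#' factor degenerates to 1.
#'
#' @param beta marginal effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @param W prior variance of the effect (default 0.04, i.e. prior SD 0.2).
#' @return numeric vector of Bayes factors, one per input record.
#' @examples
#' compute_abf(0, 0.1)            # sqrt(0.2) = 0.4472
#' compute_abf(0.5, 0.1)          # 0.4472 * exp(10)
#' @export
compute_abf <- function(beta, se, W = 0.04) {
  stop_if(any(!is.finite(beta)) || any(!is.finite(se)),
          "non-finite beta or se in association records")
  stop_if(any(se <= 0), "standard errors must be strictly positive")
  stop_if(!is.finite(W) || W < 0, "prior variance W must be >= 0")
  V <- se^2
  z <- beta / se
  sqrt(V / (V + W)) * exp(z^2 * W / (2 * (V + W)))
}

#' Fine-map one locus into a credible set
#'
#' Converts per-variant summary statistics for a single locus into posterior
#' probabilities under the single-causal-variant assumption
#' (\eqn{pp_i = ABF_i / \sum_j ABF_j}) and accumulates variants in
#' decreasing posterior order until the cumulative probability first reaches
#' the credible level (inclusive). Ties in posterior probability are broken
#' deterministically by chromosome, position, then variant id.
#'
#' Records with missing beta or se are dropped with a warning rather than
#' imputed.
#'
#' @param records data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{beta}, \code{se}, \code{locus_id}; all rows must
#'   share one \code{locus_id}.
#' @param W prior variance on the effect (default 0.04).
#' @param level credible level in (0, 1] (default 0.99).
#' @return object of class \code{credible_set}: a list with
#'   \code{locus_id}, \code{level}, \code{total_pp}, and \code{table}, a
#'   data.frame of all locus variants with columns \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{abf}, \code{pp},
#'   \code{in_credible_set}, sorted by decreasing posterior probability.
#' @export
fine_map_locus <- function(records, W = 0.04, level = 0.99) {
  stop_if(!is.data.frame(records) || nrow(records) == 0L,
          "fine_map_locus needs at least one association record")
  req <- c("variant_id", "chrom", "pos", "beta", "se", "locus_id")
  miss <- setdiff(req, names(records))
  stop_if(length(miss) > 0, "missing columns: %s", paste(miss, collapse = ", "))
  stop_if(length(unique(records$locus_id)) != 1L,
          "records span multiple locus_ids; fine-map one locus at a time")
  stop_if(!is.numeric(level) || level <= 0 || level > 1,
          "credible level must be in (0, 1]")

  bad <- !is.finite(records$beta) | !is.finite(records$se)
  if (any(bad)) {
    warning(sprintf("dropping %d record(s) with missing beta or se", sum(bad)))
    records <- records[!bad, , drop = FALSE]
    stop_if(nrow(records) == 0L, "no usable records left after dropping")
  }

  abf <- compute_abf(records$beta, records$se, W)
  pp <- abf / sum(abf)
  ord <- order(-pp, records$chrom, records$pos, records$variant_id)
  tab <- data.frame(
    variant_id = records$variant_id[ord],
    chrom = records$chrom[ord],
    pos = records$pos[ord],
    abf = abf[ord],
    pp = pp[ord],
    stringsAsFactors = FALSE
  )
  cum <- cumsum(tab$pp)
  n_in <- which(cum >= level)[1]
  if (is.na(n_in)) n_in <- nrow(tab)  # numerical guard; cum sums to 1
  tab$in_credible_set <- seq_len(nrow(tab)) <= n_in
  structure(
    list(
      locus_id = records$locus_id[1],
      level = level,
      total_pp = cum[n_in],
      table = tab
    ),
    class = "credible_set"
  )
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf(
    "Credible set for locus %s: %d / %d variants, level %.2f, total pp %.4f\n",
    x$locus_id, sum(x$table$in_credible_set), nrow(x$table),
    x$level, x$total_pp
  ))
  invisible(x)
}

#' Extract the credible variants from credible sets
#'
#' @param sets a \code{credible_set} or list of them.
#' @return data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{locus_id}, \code{pp} — one row per credible variant.
#' @export
credible_variants <- function(sets) {
  if (inherits(sets, "credible_set")) sets <- list(sets)
  out <- lapply(sets, function(cs) {
    tab <- cs$table[cs$table$in_credible_set, , drop = FALSE]
    data.frame(
      variant_id = tab$variant_id, chrom = tab$chrom, pos = tab$pos,
      locus_id = cs$locus_id, pp = tab$pp, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
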