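#' @keywords internal
#' @noRd
stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

#' Weighted pool-adjacent-violators for a non-increasing fit
#'
#' Isotonic regression under a monotone non-increasing constraint, with
#' observation weights. Used to smooth raw contact probabilities over
#' distance bins.
#'
#' @param y numeric values in distance order.
#' @param w positive weights (defaults to 1).
#' @return fitted values, non-increasing, same length as \code{y}.
#' @keywords internal
#' @noRd
pava_decreasing <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  # PAVA on -y gives a non-decreasing fit; negate back.
  yy <- -y
  level <- yy
  weight <- w
  # index of the last element of each active block
  blocks <- seq_len(n)
  i <- 1L
  nb <- n
  val <- yy
  wt <- w
  # classic stack-based PAVA
  sv <- numeric(n); sw <- numeric(n); sn <- integer(n)
  top <- 0L
  for (k in seq_len(n)) {
    top <- top + 1L
    sv[top] <- yy[k]; sw[top] <- w[k]; sn[top] <- 1L
    while (top > 1L && sv[top - 1L] > sv[top]) {
      merged_w <- sw[top - 1L] + sw[top]
      sv[top - 1L] <- (sv[top - 1L] * sw[top - 1L] + sv[top] * sw[top]) / merged_w
      sw[top - 1L] <- merged_w
      sn[top - 1L] <- sn[top - 1L] + sn[top]
      top <- top - 1L
    }
  }
  out <- numeric(n)
  pos <- 1L
  for (b in seq_len(top)) {
    out[pos:(pos + sn[b] - 1L)] <- sv[b]
    pos <- pos + sn[b]
  }
  -out
}

#' Hash a configuration list for provenance blocks
#' @keywords internal
#' @noRd
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Provenance metadata attached to pipeline outputs
#'
#' @param config list of parameters that produced an output.
#' @param seed integer seed used, if any.
#' @return list with config hash, seed, package version and timestamp-free
#'   fields suitable for JSON serialization.
#' @export
provenance_block <- function(config = list(), seed = NA_integer_) {
  list(
    config_hash = config_hash(config),
    seed = seed,
    package = "hichipTargets",
    version = as.character(utils::packageVersion("hichipTargets"))
  )
}
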