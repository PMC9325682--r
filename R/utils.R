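## Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Shannon entropy (nats) of a count or proportion vector; 0 for degenerate input.
shannon_entropy <- function(x) {
  x <- x[x > 0]
  if (length(x) <= 1L) return(0)
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' Multiplicity adjustment used for pairwise contrasts: p-values are sorted
#' ascending and the i-th smallest becomes \eqn{1 - (1 - p_{(i)})^{m - i + 1}},
#' enforced monotone by a running maximum, then returned in the original order.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' holm_sidak(c(0.01, 0.03, 0.04))
holm_sidak <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- sum(!is.na(p))
  ord <- order(p, na.last = TRUE)
  adj <- rep(NA_real_, length(p))
  running <- 0
  for (i in seq_len(m)) {
    a <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, a)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Tn5 insertion sites implied by fragments: start and end - 1 (0-based).
insertion_sites <- function(frags) {
  data.frame(
    chrom   = rep(frags$chrom, 2L),
    pos     = c(frags$start, frags$end - 1L),
    barcode = rep(frags$barcode, 2L),
    stringsAsFactors = FALSE
  )
}

# Column-standardize rows of a dense matrix (mean 0, sd 1 per row, ddof 1).
row_zscore <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  sweep(sweep(m, 1L, mu, "-"), 1L, ifelse(sd > 0, sd, NA_real_), "/")
}
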