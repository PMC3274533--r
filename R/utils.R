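#' @importFrom stats median rnorm rpois rexp rgamma runif cor phyper setNames
#' @importFrom utils read.delim write.table head tail modifyList
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package are seeded through this so that
# identical configurations give identical outputs.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Format a ratio as a percentage at reporting precision
#'
#' Headline report ratios (e.g. fraction of gene models confirmed, fraction of
#' genes with alternative splicing) are conventionally printed as percentages
#' with one decimal place.
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places of the percentage (default 1).
#' @return Numeric percentage, e.g. `as_percent(6633, 24725)` is 26.8.
#' @export
as_percent <- function(numerator, denominator, digits = 1) {
  stopifnot(denominator > 0)
  round(100 * numerator / denominator, digits)
}

#' Mean number of introns per gene
#'
#' @param n_introns Total intron (splice-site) count of the annotation.
#' @param n_genes Number of gene models.
#' @param digits Decimal places (default 2, as tabulated in cross-species
#'   splicing surveys).
#' @return Numeric ratio, e.g. `introns_per_gene(89302, 24725)` is 3.61.
#' @export
introns_per_gene <- function(n_introns, n_genes, digits = 2) {
  stopifnot(n_genes > 0)
  round(n_introns / n_genes, digits)
}

# interval helpers (1-based inclusive, integer)
iv_len <- function(start, end) pmax(0L, end - start + 1L)

iv_overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2

# message-based structured log used for dropped/ambiguous records
sr_log <- function(...) message("[splicerefine] ", sprintf(...))
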