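#' @keywords internal
"_PACKAGE"

#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- Rle runValue queryHits subjectHits
#' @importFrom stats chisq.test cor cor.test dnbinom median p.adjust pchisq
#'   quantile rbinom rlnorm rnbinom rnorm rpois runif sd setNames
#'   t.test var aov rexp ecdf IQR hclust cutree as.dist
#' @importFrom utils read.delim write.table head modifyList
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
# All generator randomness goes through this so stage toggling never perturbs
# other stages.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for a named pipeline stage, kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(offs %% 100000L)) %% 2147483629L
}

# Round half-up (away from banker's rounding) to `digits` decimal places.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
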