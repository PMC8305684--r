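#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist kmeans p.adjust phyper quantile rlnorm rnbinom
#'   rnorm runif sd t.test setNames
#' @importFrom utils read.delim write.table
NULL

# Deterministic 31-bit seed for a named substream of a root seed, so each
# emitter owns an independent RNG stream and changing one emitter's
# parameters never perturbs another's draws.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 48611) * 44257 + h * 17 + 1) %% 2147483587L
}

# Run code under a fixed seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

MOD_STATES <- c("00", "10", "01", "11")

SEX_CHROM_NAMES <- c("chrx", "chry", "x", "y")

is_sex_chrom <- function(chrom) tolower(chrom) %in% SEX_CHROM_NAMES

abort_arg <- function(...) stop(..., call. = FALSE)
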