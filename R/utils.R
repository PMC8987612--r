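# internal helpers shared across modules

# deterministic per-stage seed derived from one global seed; stays < 2^31
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

# run expr with a local RNG state so callers' streams are not disturbed
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# non-bridge sample columns in fixed display order:
# DMSO_0, DMSO_Th10, SB_0, SB_Th10, replicates ascending
sampleOrder <- function(layout) {
  ord <- c("DMSO_0", "DMSO_Th10", "SB_0", "SB_Th10")
  keep <- which(!layout$isBridge)
  keep[order(match(layout$condition[keep], ord), layout$replicate[keep])]
}

conditionColumns <- function(layout, condition) {
  which(!layout$isBridge & layout$condition == condition)
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
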