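# package-wide constants
OB_MIN_DEFAULT <- 30
DL_MIN_DEFAULT <- 0.18
CENTRALITY_MEASURES <- c("betweenness", "closeness", "degree",
                         "eigenvector", "lac", "network")

# Named RNG sub-stream: each generator mixes the master seed with its own
# stream label, so adding a generator never perturbs existing outputs.
subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

# evaluate expr under a stream-specific seed, restoring the caller's RNG
withSubSeed <- function(seed, stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(subSeed(seed, stream))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
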