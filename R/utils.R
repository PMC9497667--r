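## Internal helpers: canonical edge keys, seeded evaluation, stable seed streams.

# Canonicalise an intra-layer edge table so that from <= to lexicographically.
.canonIntra <- function(from, to) {
  swap <- from > to
  data.frame(
    from = ifelse(swap, to, from),
    to = ifelse(swap, from, to),
    stringsAsFactors = FALSE
  )
}

# Canonicalise an inter-layer edge table so (layer1, id1) <= (layer2, id2).
.canonInter <- function(layer1, id1, layer2, id2) {
  key1 <- paste(layer1, id1, sep = "\t")
  key2 <- paste(layer2, id2, sep = "\t")
  swap <- key1 > key2
  data.frame(
    layer1 = ifelse(swap, layer2, layer1),
    id1 = ifelse(swap, id2, id1),
    layer2 = ifelse(swap, layer1, layer2),
    id2 = ifelse(swap, id1, id2),
    stringsAsFactors = FALSE
  )
}

.intraKey <- function(layer, from, to) paste(layer, from, to, sep = "\t")

.interKey <- function(layer1, id1, layer2, id2) {
  paste(layer1, id1, layer2, id2, sep = "\t")
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a reproducible seed for a named random stream
#'
#' Hashes a master seed together with an arbitrary set of string/numeric tags
#' (e.g. a network name and a noise level) into a stable 31-bit seed, so that
#' each generated network, degradation and mining run draws from its own
#' independent, reproducible stream.
#'
#' @param seed Master integer seed.
#' @param ... Tags (coerced to character) identifying the stream.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @examples
#' stableSeed(1, "N1", 0.05)
#' @export
stableSeed <- function(seed, ...) {
  tags <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                       character(1)), collapse = "|")
  bytes <- utf8ToInt(tags)
  h <- as.double(seed %% 2147483647)
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

.df0 <- function(...) {
  ## zero-row data.frame with the given character columns
  cols <- c(...)
  out <- as.data.frame(stats::setNames(
    replicate(length(cols), character(0), simplify = FALSE), cols))
  out
}
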