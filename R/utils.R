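# Internal helpers: seeded RNG scoping and id/key utilities.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible 31-bit sub-seed from a master seed and string parts
# (e.g. a query pair's ids), so per-query draws are independent of execution
# order.
deriveSeed <- function(seed, ...) {
  parts <- paste(c(...), collapse = "\r")
  h <- as.double(seed) %% 2147483647
  for (cp in utf8ToInt(parts)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

pairKey <- function(protein_id, molecule_id)
  paste(protein_id, molecule_id, sep = "\t")

# round() with the conventional half-up rule, used for n- = ratio * n+
roundHalfUp <- function(x) floor(x + 0.5)
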