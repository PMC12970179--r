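# Shared internal helpers.

# round-half-away-from-zero; masking/corruption counts use this rule
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Run code with a temporary RNG state seeded by `seed`; restores the caller's
# stream so library-internal randomness never perturbs user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_invalid_molecule <- function(smiles) {
  stop(structure(class = c("molfuse_invalid_molecule", "error", "condition"),
                 list(message = paste0("invalid SMILES: ",
                                       paste(smiles, collapse = ", ")),
                      call = sys.call(-1), smiles = smiles)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
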