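# internal validators shared across modules

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s",
                  name, min, paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

check_fraction <- function(x, name, min = 0, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  as.numeric(x)
}

check_seed <- function(seed) {
  if (is.null(seed)) abort("an explicit integer `seed` is required; no global random state is used")
  check_count(seed, "seed", min = 0L)
}

# run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators never touch global randomness
with_seed <- function(seed, expr) {
  seed <- check_seed(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- rlang::`%||%`
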