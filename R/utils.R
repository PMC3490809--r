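# Internal helpers shared across modules.

# Reserved unigene token for anti-genomic background probes in layout tables.
AG_TOKEN <- "=AG="

is_ag <- function(unigene_id) unigene_id == AG_TOKEN

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s", name,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation determinism never leaks into user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Array columns of a wide probe x array tibble (everything but probe_id).
array_ids <- function(x) setdiff(names(x), "probe_id")

# Wide probe x array tibble -> numeric matrix with probe_id rownames.
wide_to_matrix <- function(x) {
  m <- as.matrix(x[array_ids(x)])
  rownames(m) <- x$probe_id
  m
}

matrix_to_wide <- function(m) {
  out <- as_tibble(m)
  out <- tibble(probe_id = rownames(m), !!!out)
  out
}
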