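# Internal helpers shared across the package.

# All lexicographic rules in the layout algorithms compare strings byte-wise
# (C locale), independent of the user's locale. sort()/order() with
# method = "radix" guarantee that for character vectors.
c_sort <- function(x) sort(x, method = "radix")

c_order <- function(...) order(..., method = "radix")

# Integer codes such that code(a) < code(b) iff a < b byte-wise.
# Used where two character vectors must be compared element-wise.
c_codes <- function(...) {
  vecs <- list(...)
  lev <- c_sort(unique(unlist(vecs, use.names = FALSE)))
  lapply(vecs, match, table = lev)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Condition constructors so the CLI can map error classes to exit codes.
fabric_error <- function(msg, class = "fabric_error", call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fabric_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

parse_error <- function(msg) fabric_error(msg, class = "fabric_parse_error")
validation_error <- function(msg) fabric_error(msg, class = "fabric_validation_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
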