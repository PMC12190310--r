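# internal helpers shared across modules

# apply f to every numeric leaf of a nested list, preserving structure
tree_map <- function(x, f) {
  if (is.list(x)) return(lapply(x, tree_map, f = f))
  f(x)
}

# combine two structurally identical trees leaf-wise; children are
# matched by name where names exist, by position otherwise
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
    return(mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE))
  }
  f(a, b)
}

# sum of f over numeric leaves (used for gradient checks / diagnostics)
tree_reduce <- function(x, f, acc = 0) {
  if (is.list(x)) {
    for (el in x) acc <- tree_reduce(el, f, acc)
    return(acc)
  }
  acc + f(x)
}

# run code under a temporary seed without disturbing the caller's RNG;
# seed = NULL uses the current RNG stream
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seq_len that tolerates 0 inside indexing pipelines
seq_len2 <- function(n) seq_len(max(n, 0L))

stop_mmdda <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mmdda_error")))
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_mmdda(sprintf("'%s' must be a finite numeric scalar", name),
               "mmdda_config_error")
  ok <- if (strict) x > lower else x >= lower
  if (!ok)
    stop_mmdda(sprintf("'%s' must be %s %s", name,
                       if (strict) "greater than" else "at least", lower),
               "mmdda_config_error")
  invisible(x)
}
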