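# Utilities over nested parameter lists (numeric leaves).

param_map <- function(f, a, b = NULL) {
  if (is.numeric(a)) return(if (is.null(b)) f(a) else f(a, b))
  out <- a
  for (i in seq_along(a))
    out[[i]] <- param_map(f, a[[i]], if (is.null(b)) NULL else b[[i]])
  out
}

param_add <- function(a, b) param_map(`+`, a, b)
param_scale <- function(a, s) param_map(function(x) x * s, a)
param_zero <- function(a) param_map(function(x) x * 0, a)

param_unlist <- function(a) {
  if (is.numeric(a)) return(as.numeric(a))
  unlist(lapply(a, param_unlist), use.names = FALSE)
}

param_count <- function(a) length(param_unlist(a))

param_finite <- function(a) all(is.finite(param_unlist(a)))

# overwrite the leaves of `a` with consecutive entries of numeric vector `v`
param_relist <- function(a, v) {
  pos <- 0L
  walk <- function(x) {
    if (is.numeric(x)) {
      n <- length(x)
      x[] <- v[pos + seq_len(n)]
      pos <<- pos + n
      return(x)
    }
    for (i in seq_along(x)) x[[i]] <- walk(x[[i]])
    x
  }
  out <- walk(a)
  stopifnot(pos == length(v))
  out
}
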