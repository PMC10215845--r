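# Internal helpers shared across modules.

# Classed conditions so callers (and tests) can distinguish failure modes.
abort_mhd <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mhdnet_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_io         <- function(msg) abort_mhd(msg, "mhdnet_io_error")
stop_format     <- function(msg) abort_mhd(msg, "mhdnet_format_error")
stop_annotation <- function(msg) abort_mhd(msg, "mhdnet_annotation_error")
stop_config     <- function(msg) abort_mhd(msg, "mhdnet_config_error")
stop_value      <- function(msg) abort_mhd(msg, "mhdnet_value_error")
stop_contract   <- function(msg) abort_mhd(msg, "mhdnet_contract_error")
stop_shape      <- function(msg) abort_mhd(msg, "mhdnet_shape_error")
stop_leakage    <- function(msg) abort_mhd(msg, "mhdnet_leakage_error")
stop_parameter  <- function(msg) abort_mhd(msg, "mhdnet_parameter_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic 31-bit seed derived from a base seed and a string tag.
derive_seed <- function(seed, tag) {
  h <- 0
  for (v in utf8ToInt(as.character(tag))) h <- (h * 131 + v) %% 1000000007
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Apply f to every numeric leaf of a (possibly nested) parameter list.
ptree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(el) ptree_map(f, el))
    attributes(out) <- attributes(a)
    out
  } else f(a)
}

# Apply f leafwise over two parameter trees with identical structure.
ptree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) ptree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else f(a, b)
}

# Sum f(leaf) over a parameter tree.
ptree_sum <- function(f, a) {
  if (is.list(a)) sum(vapply(a, function(el) ptree_sum(f, el), numeric(1)))
  else f(a)
}

# Concatenate two [C, L, B] arrays along the channel axis.
chan_cat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

as_cube <- function(x) {
  if (length(dim(x)) == 3L) x
  else if (is.matrix(x)) array(x, c(dim(x), 1L))
  else array(x, c(1L, length(x), 1L))
}

sigmoid <- function(z) 1 / (1 + exp(-z))
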