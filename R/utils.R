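## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Canonical unordered pair key.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

stop_if_not_class <- function(x, cls, arg) {
  if (!inherits(x, cls))
    stop(sprintf("'%s' must be a <%s> object", arg, cls), call. = FALSE)
}

## Sample labels are "<condition>_<replicate>"; T0 samples use the reserved
## condition "T0". Condition names therefore must not contain "_".
sample_condition <- function(labels) sub("_[^_]+$", "", labels)
sample_replicate <- function(labels) sub("^.*_", "", labels)
sample_label <- function(condition, replicate) paste(condition, replicate, sep = "_")
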