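`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# semicolon-joined EC tuple <-> character vector
splitEcs <- function(x) strsplit(x, ";", fixed = TRUE)
joinEcs <- function(x) paste(x, collapse = ";")

stopIfNot1String <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(sprintf("%s must be a single string", what), call. = FALSE)
}
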