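# internal helpers shared across modules

# round half away from zero; base round() is banker's rounding
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

clip01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == trunc(x)

# order pairs so i < j, given two integer vectors
normalize_pairs <- function(i, j) {
  swap <- i > j
  tmp <- i[swap]
  i[swap] <- j[swap]
  j[swap] <- tmp
  cbind(i = as.integer(i), j = as.integer(j))
}

pair_key <- function(i, j, L) (as.numeric(i) - 1) * L + as.numeric(j)

# run code under a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}
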