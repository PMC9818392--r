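# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
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
  }, add = TRUE)
  set.seed(seed)
  code
}

# derive a 31-bit stream seed from a base seed and an index
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483629)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

is_binary <- function(x, tol = 0) all(x %in% c(0, 1))

# coerce an (h, w, c) image or list of them into an (h, w, c, n) batch
as_batch <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  stopifnot(is.list(images), length(images) >= 1L)
  d <- dim(images[[1]])
  out <- array(0, dim = c(d, length(images)))
  for (i in seq_along(images)) {
    di <- dim(images[[i]])
    if (!all(di == d)) {
      stop(sprintf("image %d has dimensions %s; expected %s", i,
                   paste(di, collapse = "x"), paste(d, collapse = "x")),
           call. = FALSE)
    }
    out[, , , i] <- images[[i]]
  }
  out
}

# sample one element of a vector (unlike sample(), safe for length-1 input)
sample_from <- function(v) if (length(v) == 1L) v else sample(v, 1L)
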