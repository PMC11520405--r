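#' @useDynLib refocus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median quantile sd var
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  `seed = NULL` uses the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed
#'
#' Splitmix-style mixing of a parent seed and a stream index, so derived
#' streams (e.g. the K samples of [restore_averaged()]) do not depend on call
#' order.  The result is an integer-valued double in `[0, 2^31)`.
#'
#' @param seed Parent seed (non-negative integer-valued scalar).
#' @param k Stream index.
#' @return A single integer-valued numeric.
#' @export
sub_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k), length(k) == 1)
  mix_seed_cpp(as.double(seed), as.double(k))
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_image <- function(x) is.matrix(x) && is.numeric(x)

check_image01 <- function(x, what = "image") {
  if (!is_image(x)) stop(what, " must be a numeric matrix", call. = FALSE)
  if (anyNA(x) || min(x) < -1e-9 || max(x) > 1 + 1e-9) {
    stop(what, " must have values in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# Tiny polynomial rolling hash of a character vector (config fingerprints
# for the run log; not cryptographic).
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
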