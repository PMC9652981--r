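#' @useDynLib gtvseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile sd
NULL

# Run `code` under a temporary RNG state seeded with `seed`; the caller's RNG
# state is untouched, so seeded functions compose without side effects.
with_seed_ <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named child seed from a master seed
#'
#' One integer master seed spawns independent named streams (for example
#' `"geometry"` and `"noise"` inside the phantom generator, or `"case3"`
#' inside dataset generation), so changing one stream's consumption never
#' shifts another. The map is a fixed integer hash; results stay below 2^31.
#'
#' @param seed Integer master seed.
#' @param name Character stream name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  s <- (abs(seed) %% 2147483647) * 69069 %% 2147483647
  as.integer((s + h * 2477 + 1) %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gtv <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

axis_names <- c("depth", "height", "width")
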