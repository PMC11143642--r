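# Internal helpers shared across modules.

CULTIVARS <- c("Atabaki", "Faroogh", "Shirineshahvar")
TRAITS <- c("LN", "PR", "ES", "SL")
GA3_LEVELS <- c(0, 0.1, 0.25, 0.5)
ZT_LEVELS <- c(0, 0.25, 0.5, 0.75)
MODEL_KINDS <- c("XGB", "RF", "SVR", "ENMLR", "ESR")
BASE_KINDS <- c("XGB", "SVR", "ENMLR")

# Experimental dose rectangle (mg/L); surrogates and the optimizer stay inside it.
DOSE_BOUNDS <- list(ga3 = c(0, 0.5), zt = c(0, 0.75))

# Column of the observation table holding a trait.
trait_column <- function(trait) {
  switch(trait,
    LN = "LN", PR = "PR", ES = "ES_pct", SL = "SL_cm",
    stop("unknown trait: ", trait)
  )
}

# Valid range of a trait, used for clipping generated replicates and reported
# predictions (survival is a percentage; the others are nonnegative).
trait_range <- function(trait) {
  if (trait == "ES") c(0, 100) else c(0, Inf)
}

clip_trait <- function(x, trait) {
  r <- trait_range(trait)
  pmin(pmax(x, r[1]), r[2])
}

#' Derive a reproducible substream seed
#'
#' Hashes a root seed together with any number of string/numeric labels into an
#' integer seed below 2^31, so that independent pipeline stages (data
#' generation, splitting, tuning, optimization) each consume their own RNG
#' stream regardless of execution order.
#'
#' @param seed Integer root seed.
#' @param ... Labels (coerced to character) identifying the substream.
#' @return A single integer in [0, 2^31 - 2].
#' @export
substream_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                         character(1)), collapse = "|")
  bytes <- utf8ToInt(paste0(format(seed), "#", labels))
  h <- 17
  # polynomial rolling hash mod the Mersenne prime 2^31 - 1; intermediate
  # products stay below 2^53 so double arithmetic is exact
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Evaluate fn() with its own temporary RNG stream, restoring the caller's
# stream afterwards. Keeps samplers' streams insulated from model backends.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  fn()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a packaged fixture
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return A file path (or vector of file names).
#' @export
culturopt_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "culturopt")))
  }
  path <- system.file("extdata", file, package = "culturopt")
  if (!nzchar(path)) stop("no packaged fixture named ", file)
  path
}
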