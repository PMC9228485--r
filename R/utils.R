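# Internal helpers: seeded evaluation, seed fan-out, unit conversion.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a global seed
#'
#' One global integer reproduces every stage of a pipeline run: each stage
#' draws its own seed as a deterministic hash of the global seed and the
#' stage name, kept within the 32-bit signed integer range.
#'
#' @param seed global integer seed.
#' @param stage character stage tag, e.g. \code{"synth-piv"}.
#' @return a positive integer seed below 2^31.
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% 2147483629) + 1L
}

UM <- 1e-6             # metres per micrometre
ML_PER_H <- 1 / 3.6e9  # m^3/s per mL/h

umToM <- function(x) x * UM
mToUm <- function(x) x / UM
m3sToMlh <- function(x) x / ML_PER_H
mlhToM3s <- function(x) x * ML_PER_H

# Quantize a real-valued intensity raster to the 8-bit range.
quantize8 <- function(img) {
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

stopIfNot8bitish <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a numeric intensity matrix")
  invisible(img)
}
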