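#' @importFrom stats lm coef cor.test pt rnorm runif rexp sd var approx
#' @importFrom utils head tail read.table write.table
NULL

## Gas constant in kJ mol^-1 K^-1
.R_GAS <- 8.314462618e-3

## nm^2 -> Angstrom^2; applied only when reporting areas
.NM2_TO_A2 <- 100

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG
#' state, so generators are bit-reproducible without disturbing the session.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## log(sum(exp(x))) without overflow; x may contain -Inf
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## wrap coordinates into [0, L) per axis
wrapPositions <- function(pos, box) {
  for (k in 1:3) pos[, k] <- pos[, k] - box[k] * floor(pos[, k] / box[k])
  pos
}

## minimum-image displacement in one periodic dimension
minImage <- function(d, L) d - L * round(d / L)

## minimum-image xy distance between points and a reference (x0, y0)
minImageDistXY <- function(x, y, x0, y0, box) {
  dx <- minImage(x - x0, box[1])
  dy <- minImage(y - y0, box[2])
  sqrt(dx * dx + dy * dy)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
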