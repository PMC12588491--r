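#' @import methods
#' @importFrom stats rnorm runif rpois sd quantile var dnorm pnorm dpois
#'   qnorm median setNames predict rbinom complete.cases
#' @importFrom utils read.csv write.csv head modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib HetTabGen, .registration = TRUE
NULL

ATTRIBUTE_DTYPES <- c("real", "positive", "count", "categorical",
                      "ordered_categorical")
NUMERIC_DTYPES <- c("real", "positive", "count")
LEVEL_DTYPES <- c("categorical", "ordered_categorical")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package
#' operations do not disturb the caller's random stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (hadSeed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Leafwise walk over parallel nested parameter lists. f receives one leaf
# from each structure; NULL leaves are passed through untouched.
mapLeaves <- function(f, x, ...) {
  others <- list(...)
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) {
      out[[i]] <- do.call(mapLeaves,
                          c(list(f, x[[i]]), lapply(others, `[[`, i)))
    }
    out
  } else if (is.null(x)) {
    NULL
  } else {
    do.call(f, c(list(x), others))
  }
}

sumLeaves <- function(x, f) {
  tot <- 0
  walk <- function(v) {
    if (is.list(v)) lapply(v, walk)
    else if (!is.null(v)) tot <<- tot + f(v)
    invisible(NULL)
  }
  walk(x)
  tot
}

#' Append a JSON-lines log entry
#' @noRd
jlog <- function(event, ..., file = getOption("HetTabGen.log", NULL),
                 level = "info") {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  level = level, event = event), list(...))
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE)
  if (is.null(file)) {
    if (identical(getOption("HetTabGen.verbose", FALSE), TRUE))
      message(line)
  } else {
    cat(line, "\n", sep = "", file = file, append = TRUE)
  }
  invisible(NULL)
}

# Stable short hash of an R object (used to stamp artifacts with the schema
# they were produced under; not cryptographic).
shortHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  raw <- utf8ToInt(s)
  h <- 5381
  for (v in raw) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}
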