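#' @useDynLib ctcscope, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rnorm rpois runif var
#' @importFrom utils read.csv write.csv
NULL

# Imaging channels, in canonical order (nuclear, cytokeratin, PSMA, CD45).
CHANNELS <- c("blue", "green", "orange", "red")

PHENOTYPES <- c("CTC", "WBC", "NUCLEATED_OTHER")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Tag a matrix as a grayscale image
#'
#' Images throughout the package are plain numeric matrices of
#' integer-valued digital numbers (row = y, column = x), carrying a
#' `bit_depth` attribute (8 or 16) that fixes the dtype maximum used by
#' saturation, window/level and file output.
#'
#' @param mat Numeric matrix of pixel values.
#' @param bit_depth Digitiser depth in bits.
#' @return `mat` with a `bit_depth` attribute.
#' @export
new_image <- function(mat, bit_depth = 16L) {
  attr(mat, "bit_depth") <- as.integer(bit_depth)
  mat
}

image_bit_depth <- function(img) {
  bd <- attr(img, "bit_depth")
  if (is.null(bd)) if (max(img) > 255) 16L else 8L else as.integer(bd)
}

image_max_value <- function(img) 2^image_bit_depth(img) - 1

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

log_params <- function(op, ...) {
  if (!isTRUE(getOption("ctcscope.verbose", FALSE))) return(invisible(NULL))
  args <- list(...)
  kv <- paste(names(args), vapply(args, function(a)
    paste(format(a, digits = 6), collapse = ","), ""), sep = "=",
    collapse = " ")
  message(sprintf("[ctcscope] %s %s", op, kv))
  invisible(NULL)
}
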