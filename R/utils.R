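## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Independent pseudo-random streams for pipeline stages (and for the rows of
#' an association scan) are obtained by mixing the master seed with a
#' label-dependent hash.  The result always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param label character label naming the stream (e.g. a stage name).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(label), length(label) == 1L)
  cp <- utf8ToInt(label)
  h <- sum(cp * seq_along(cp)) + length(cp) * 131L
  as.integer((abs(as.numeric(master)) * 7919 + h * 104729) %% 2147483629)
}

## Consistent numeric coding of character covariates used in design matrices.
## Documented convention: sex F = 0, M = 1; handedness R = 0, L = 1;
## group HC = 0, PD = 1.
.covariate_codings <- list(
  sex        = c(F = 0, M = 1),
  handedness = c(R = 0, L = 1),
  group      = c(HC = 0, PD = 1)
)

.as_numeric_column <- function(data, name) {
  if (!name %in% names(data)) {
    stop("column '", name, "' not found in data", call. = FALSE)
  }
  x <- data[[name]]
  if (is.numeric(x)) return(as.numeric(x))
  if (is.factor(x)) x <- as.character(x)
  if (name %in% names(.covariate_codings)) {
    coding <- .covariate_codings[[name]]
    out <- unname(coding[x])
    if (anyNA(out) && !anyNA(x)) {
      stop("column '", name, "' contains levels outside ",
           paste(names(coding), collapse = "/"), call. = FALSE)
    }
    return(as.numeric(out))
  }
  stop("column '", name, "' is non-numeric and has no declared coding",
       call. = FALSE)
}

.check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("'", name, "' must be a single value in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == round(x)
}
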