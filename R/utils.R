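# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so stochastic functions are reproducible without clobbering the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer 'seed' is required for this stochastic operation")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# extreme test statistics can underflow to p = 0; keep p-values in (0, 1]
clamp_p <- function(p) pmax(p, 1e-300)

#' Stop unless a data frame has the named columns
#' @noRd
check_columns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, colnames(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

#' MD5 of an R object's canonical YAML rendering (for run manifests)
#' @noRd
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(x), tmp)
  unname(tools::md5sum(tmp))
}

#' Z-scoring of a numeric vector (sample sd)
#' @noRd
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero-variance vector cannot be standardized")
  (x - mean(x)) / s
}

#' Unrank an index into an unordered pair (i < j) among m items
#'
#' Pairs are ordered (1,2), (1,3), ..., (1,m), (2,3), ...; used to sample
#' distinct protein pairs without materializing all of them.
#' @noRd
unrank_pair <- function(idx, m) {
  # i is the largest value with cumulative count < idx
  cum <- cumsum((m - 1):1)
  i <- findInterval(idx - 1L, c(0, cum), rightmost.closed = FALSE)
  prev <- c(0, cum)[i]
  j <- i + (idx - prev)
  cbind(i = i, j = j)
}
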