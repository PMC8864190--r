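`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Stable 31-bit hash of the master seed together with any number of string
#' keys (stage names, cell ids, replicate indices).  Used throughout the
#' package so that per-cell and per-stage random streams are independent but
#' fully determined by a single master seed.
#'
#' @param master Integer master seed.
#' @param ... Further key components, coerced to character.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "simulate", "cell_003")
#' @export
derive_seed <- function(master, ...) {
  key <- paste(
    c(as.character(master), vapply(list(...), function(k) paste(as.character(k), collapse = ","), "")),
    collapse = "/"
  )
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

## length-weighted median (used for the diploid baseline of a cell)
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

## first element of runs; returns integer run ids for a vector
run_ids <- function(x) {
  if (length(x) == 0L) return(integer(0))
  cumsum(c(1L, as.integer(x[-1L] != x[-length(x)])))
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
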