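# Internal helpers shared across the package.

#' Clamp values into a closed interval
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Enumerate all permutations of 1..n (n <= 9)
#' @noRd
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

#' Maximum-sum assignment of rows to columns of a square score matrix
#'
#' Exhaustive for n <= 8, greedy otherwise. Returns `perm` with
#' `perm[i]` the column matched to row `i`.
#' @noRd
best_assignment <- function(score) {
  n <- nrow(score)
  stopifnot(ncol(score) == n)
  if (n <= 8L) {
    perms <- all_permutations(n)
    totals <- apply(perms, 1L, function(p) sum(score[cbind(seq_len(n), p)]))
    return(perms[which.max(totals), ])
  }
  perm <- integer(n)
  free <- seq_len(n)
  for (i in order(-apply(score, 1L, max))) {
    j <- free[which.max(score[i, free])]
    perm[i] <- j
    free <- setdiff(free, j)
  }
  perm
}

#' Write a named list as a JSON sidecar
#' @noRd
write_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample from a vector without the scalar-`sample()` pitfall
#' @noRd
resample <- function(x, n) x[sample.int(length(x), n)]
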