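#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' simulation helpers are deterministic without perturbing the session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Default cell-type names
#'
#' The first three types are named after the three differentiating-xylem cell
#' types (libriform fibers, vessel elements, ray parenchyma); beyond three,
#' generic names are used.
#' @param n_types number of types.
#' @return character vector of length `n_types`.
#' @keywords internal
#' @noRd
default_type_names <- function(n_types) {
  base <- c("fiber", "vessel", "ray")
  if (n_types <= length(base)) {
    base[seq_len(n_types)]
  } else {
    c(base, sprintf("type%02d", seq(length(base) + 1L, n_types)))
  }
}

# lexicographic sort independent of the session locale
sort_c <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
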