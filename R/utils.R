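#' @importFrom stats optimize optim pchisq plogis qt sd glm binomial lm anova
#'   rbinom runif setNames coef pf wilcox.test t.test ks.test
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Run an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

#' Reverse complement of a nucleotide string
#'
#' Gaps (`-`) and `N` are preserved; lowercase input is uppercased.
#'
#' @param x character scalar over `A,C,G,T,N,-`.
#' @return reverse-complemented character scalar.
#' @keywords internal
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  chartr("ACGTNacgtn", "TGCANTGCAN",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# split a string into single characters
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Derive a bounded child seed from a master seed
#'
#' Keeps derived seeds below 2^31 so they remain valid R integers.
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1103 * k) %% 2147483587) + 1L
}

pkg_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}
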