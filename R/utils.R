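# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' All stochastic stages draw their seeds from one master seed through this
#' rule, so a whole pipeline run is reproducible from a single integer.
#' The derived seed stays below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param stream integer stream index (>= 0); distinct streams give
#'   distinct, deterministic child seeds.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  # Weyl-style mixing on the 2^31-1 field; cheap, documented, collision-safe
  # for the handful of streams a run uses.
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  for (i in seq_len(2L)) s <- (s * 48271 + 7919 * (stream + 1)) %% m
  as.integer(s %% (m - 2) + 1)
}

# run expr with a local RNG state (restores caller's .Random.seed)
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# consistent TSV writers/readers
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
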