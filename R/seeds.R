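#' Derive a deterministic child seed for a named generator stream
#'
#' One user-facing seed is expanded into independent per-submodule seeds by
#' a counter-based scheme: each stream owns a fixed counter, so adding a new
#' generator never perturbs the draws of existing ones. Streams used by the
#' simulators are fixed at package level; the gene-class stream is shared by
#' the expression and ATAC simulators so both see the same SE/TE gene
#' assignment.
#'
#' @param seed integer master seed.
#' @param stream character stream name (see `names(sehet:::.seed_streams)`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.finite(seed), length(stream) == 1)
  counter <- .seed_streams[[stream]]
  if (is.null(counter)) stop("unknown seed stream: ", stream)
  m <- 2147483629 # large prime below 2^31
  x <- (as.double(seed) %% m) * 69069 + counter * 1234567 + 987654321
  as.integer(x %% m + 1)
}

.seed_streams <- c(
  gene_class   = 1L,
  expression   = 2L,
  atac_layout  = 3L,
  atac_counts  = 4L,
  foci         = 5L,
  undersample  = 6L,
  genome       = 7L,
  pipeline     = 8L
)
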