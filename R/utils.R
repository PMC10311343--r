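# Internal helpers shared across modules.

PERTURBATION_NODE <- "PERTURBATION"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
split_list_cell <- function(x, sep = ";") {
  if (length(x) == 0L || is.na(x) || !nzchar(x)) return(character(0))
  out <- strsplit(x, sep, fixed = TRUE)[[1L]]
  out <- trimws(out)
  out[nzchar(out)]
}

#' @noRd
join_list_cell <- function(x, sep = ";") paste(sort(unique(x)), collapse = sep)

# Canonical undirected keys: endpoints ordered lexicographically so that the
# same interaction always hashes to the same string.
ddi_key <- function(pa, da, pb, db) paste(pa, da, pb, db, sep = "|")
ppi_key <- function(pa, pb) paste(pa, pb, sep = "|")

# TRUE where side b sorts before side a under (protein, domain) ordering.
needs_swap <- function(pa, da, pb, db) {
  (pb < pa) | (pb == pa & db < da)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls stay side-effect free.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stable sub-seed derivation (kept well below .Machine$integer.max).
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483629)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
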