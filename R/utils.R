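## Internal helpers: seeded RNG scoping, seed substreams, unit conversions.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package operations do not
#' disturb the caller's RNG stream.
#' @noRd
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
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' Deterministic substreams so that toggling pipeline stages does not shift
#' the seeds of the remaining stages. Kept within 32-bit integer range.
#' @noRd
spawn_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(flow = 101L, metrics = 211L, cohort = 307L, analyze = 401L,
               phantom = 503L, gating = 601L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else 701L
  as.integer((as.numeric(seed) * 2654435L + off * 40503L) %% 2147483647L)
}

## Flow unit conversions. Internal convention: geometry mm, velocity cm/s,
## flow ml/s (= cm^3/s).
MM2_TO_CM2 <- 0.01

ml_s_to_ml_min <- function(x) x * 60

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
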