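# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
qb_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "quenchbind_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

format_error <- function(msg) qb_stop(msg, "quenchbind_format_error")
precondition_error <- function(msg) qb_stop(msg, "quenchbind_precondition_error")
validation_error <- function(msg) qb_stop(msg, "quenchbind_validation_error")

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

is_strictly_increasing <- function(x) {
  length(x) < 2L || all(diff(x) > 0)
}

# Decimal text at full double precision, for lossless CSV round trips.
num_to_text <- function(x) {
  formatC(x, digits = 17, format = "g", mode = "double")
}

#' Gas constant in J/(mol K)
#' @keywords internal
#' @noRd
R_GAS <- 8.314
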