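# Internal validators shared across modules.

stop_invalid <- function(msg, class = "isoniche_invalid_input") {
  rlang::abort(msg, class = class)
}

assert_simplex <- function(p, tol = 1e-8, what = "p") {
  if (any(!is.finite(p))) {
    stop_invalid(sprintf("`%s` contains non-finite values.", what))
  }
  if (any(p < -tol)) {
    stop_invalid(sprintf("`%s` has negative components.", what))
  }
  if (abs(sum(p) - 1) > max(tol, 1e-6)) {
    stop_invalid(sprintf("`%s` must sum to 1 (got %.8f).", what, sum(p)))
  }
  invisible(TRUE)
}

# Renormalize a nonnegative vector onto the simplex.
renormalize <- function(p) {
  p <- pmax(p, 0)
  p / sum(p)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf(
        "%s is missing required column(s): %s",
        what, paste(missing, collapse = ", ")
      ),
      class = "isoniche_schema_error"
    )
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
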