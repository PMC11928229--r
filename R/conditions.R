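# Typed error conditions. Every operational failure signals a condition of
# class "charrec_<kind>_error" so callers (and the CLI) can branch on the
# failure mode rather than match message text.

stop_charrec <- function(msg, class, data = list(), call. = FALSE) {
  cond <- structure(
    class = c(paste0("charrec_", class, "_error"), "charrec_error",
              "error", "condition"),
    c(list(message = msg, call = NULL), data)
  )
  stop(cond)
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x
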