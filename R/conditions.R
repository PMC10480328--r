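# typed conditions so callers can distinguish "not an RT plan" from
# validation failures when scanning mixed directories

uf_stop <- function(subclass, message, ...) {
  stop(structure(
    class = c(subclass, "uf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

stop_not_rtplan <- function(path, why) {
  uf_stop("uf_not_rtplan",
          sprintf("not an RT plan: %s (%s)", path, why), path = path)
}

stop_validation <- function(message, ...) {
  uf_stop("uf_validation", message, ...)
}

stop_no_reference <- function(name, width_deg) {
  uf_stop("uf_no_reference",
          sprintf("no built-in reference '%s' at %d degree intervals", name,
                  as.integer(width_deg)))
}

stop_empty <- function(message) uf_stop("uf_empty", message)
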