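# Classed conditions so callers (and the CLI) can map failures to exit codes.

pgx_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "pgxdip_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

pgx_usage_error  <- function(msg, ...) pgx_stop(msg, "pgxdip_usage_error", ...)
pgx_schema_error <- function(msg, ...) pgx_stop(msg, "pgxdip_schema_error", ...)
pgx_input_error  <- function(msg, ...) pgx_stop(msg, "pgxdip_input_error", ...)
pgx_state_error  <- function(msg, ...) pgx_stop(msg, "pgxdip_state_error", ...)
pgx_lookup_error <- function(msg, ...) pgx_stop(msg, "pgxdip_lookup_error", ...)
pgx_template_error <- function(msg, ...) pgx_stop(msg, "pgxdip_template_error", ...)
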