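# Structured error conditions. Every user-facing failure carries a subclass
# of "dockscape_error" so callers (and the pipeline driver) can branch on the
# failure kind rather than on message text.

ds_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "dockscape_error")))
}

ds_format_error    <- function(fmt, ...) ds_stop("dockscape_format_error", fmt, ...)
ds_label_error     <- function(fmt, ...) ds_stop("dockscape_label_error", fmt, ...)
ds_reference_error <- function(fmt, ...) ds_stop("dockscape_reference_error", fmt, ...)
ds_value_error     <- function(fmt, ...) ds_stop("dockscape_value_error", fmt, ...)
ds_usage_error     <- function(fmt, ...) ds_stop("dockscape_usage_error", fmt, ...)
ds_bounds_error    <- function(fmt, ...) ds_stop("dockscape_bounds_error", fmt, ...)
ds_config_error    <- function(fmt, ...) ds_stop("dockscape_config_error", fmt, ...)

#' @noRd
AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")
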