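# Lightweight publish/subscribe bus mirroring the signal wiring between
# the framework's components: units connect their processing functions to
# named events ("new_files", "script_finished", "reconstruct",
# "execution_finished", "layer_added") instead of calling each other, and
# tests subscribe observers to the same hooks.

#' Create an event bus
#'
#' @return An `event_bus` environment.
#' @export
event_bus <- function() {
  b <- new.env(parent = emptyenv())
  b$subs <- list()
  class(b) <- c("event_bus", class(b))
  b
}

#' Subscribe a function to an event
#'
#' @param bus An [event_bus()].
#' @param event Event name.
#' @param fn Function called with the emitter's arguments.
#' @return The bus, invisibly.
#' @export
subscribe <- function(bus, event, fn) {
  stopifnot(inherits(bus, "event_bus"), is.function(fn))
  bus$subs[[event]] <- c(bus$subs[[event]], fn)
  invisible(bus)
}

#' Emit an event
#'
#' Calls every subscriber of `event` in subscription order. Subscriber
#' errors propagate to the emitter (the unit's handler layer converts
#' them into failed execution records).
#'
#' @param bus An [event_bus()].
#' @param event Event name.
#' @param ... Arguments forwarded to the subscribers.
#' @return Number of subscribers called, invisibly.
#' @export
emit <- function(bus, event, ...) {
  fns <- bus$subs[[event]]
  for (fn in fns) fn(...)
  invisible(length(fns))
}
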