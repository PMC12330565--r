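# Generics and accessors for the data containers.

#' @rdname accessors
#' @param object a data container.
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' Accessors
#'
#' Accessor functions for \linkS4class{Waveform},
#' \linkS4class{Electrodogram} and \linkS4class{Nervegram} objects.
#'
#' @name accessors
#' @aliases sampleRate duration samples levelDb currentMatrix currentDb
#'   rates spikes channelCfs electrodePositions
NULL

#' @rdname accessors
#' @export
setMethod("sampleRate", "Waveform", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("sampleRate", "Electrodogram", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("sampleRate", "Nervegram", function(object) object@fs)

#' @rdname accessors
#' @export
setMethod("duration", "Waveform",
          function(object) length(object@samples) / object@fs)
#' @rdname accessors
#' @export
setMethod("duration", "Electrodogram",
          function(object) ncol(object@current) / object@fs)
#' @rdname accessors
#' @export
setMethod("duration", "Nervegram",
          function(object) dim(object@rates)[2] / object@fs)

#' @rdname accessors
#' @param w a \linkS4class{Waveform}.
#' @export
samples <- function(w) w@samples

#' @rdname accessors
#' @export
levelDb <- function(w) w@levelDb

#' @rdname accessors
#' @param eg an \linkS4class{Electrodogram}.
#' @return \code{currentMatrix}: M x T matrix of linear current (mA).
#' @export
currentMatrix <- function(eg) eg@current

#' @rdname accessors
#' @return \code{currentDb}: M x T matrix of current level (dB re 1 mA) at
#'   pulse samples and \code{NA} elsewhere.
#' @export
currentDb <- function(eg) {
  m <- eg@current
  out <- matrix(NA_real_, nrow(m), ncol(m))
  nz <- m > 0
  out[nz] <- 20 * log10(m[nz])
  out
}

#' @rdname accessors
#' @param ng a \linkS4class{Nervegram}.
#' @export
rates <- function(ng) ng@rates

#' @rdname accessors
#' @export
spikes <- function(ng) ng@spikes

#' @rdname accessors
#' @export
channelCfs <- function(ng) ng@channelCfs

#' @rdname accessors
#' @export
electrodePositions <- function(eg) eg@positionsMm
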