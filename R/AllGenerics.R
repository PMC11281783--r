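# Generics for the package's S4 accessors.

#' @rdname CalciumSession-accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname CalciumSession-accessors
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))

#' @rdname CalciumSession-accessors
#' @export
setGeneric("rawF", function(x) standardGeneric("rawF"))

#' @rdname CalciumSession-accessors
#' @export
setGeneric("behaviorChannel",
           function(x, channel) standardGeneric("behaviorChannel"))

#' @rdname CalciumSession-accessors
#' @export
setGeneric("velocity", function(x) standardGeneric("velocity"))

#' @rdname CalciumSession-accessors
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' @rdname CalciumSession-accessors
#' @export
setGeneric("sessionEvents", function(x) standardGeneric("sessionEvents"))

#' @rdname CalciumSession-accessors
#' @export
setGeneric("sessionEvents<-",
           function(x, value) standardGeneric("sessionEvents<-"))

#' @rdname CalciumSession-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname CalciumSession-accessors
#' @export
setGeneric("unitInfo", function(x) standardGeneric("unitInfo"))

#' @rdname ETAResult-accessors
#' @export
setGeneric("meanTrace", function(x) standardGeneric("meanTrace"))

#' @rdname ETAResult-accessors
#' @export
setGeneric("responseScalars", function(x) standardGeneric("responseScalars"))

#' @rdname ETAResult-accessors
#' @export
setGeneric("snippetTime", function(x) standardGeneric("snippetTime"))

#' @rdname ETAResult-accessors
#' @export
setGeneric("nOnsets", function(x) standardGeneric("nOnsets"))

#' @rdname HBootResult-accessors
#' @export
setGeneric("bootMeans", function(x) standardGeneric("bootMeans"))

#' @rdname HBootResult-accessors
#' @export
setGeneric("bootCI", function(x) standardGeneric("bootCI"))

#' @rdname HBootResult-accessors
#' @export
setGeneric("pValue",
           function(x, alternative = c("one.sided", "two.sided"))
             standardGeneric("pValue"))
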