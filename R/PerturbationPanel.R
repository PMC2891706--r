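#' Construct a perturbation panel
#'
#' @param component character vector of unique signaling-component names
#'   (at least 2).
#' @param sign perturbation direction per component: -1 for inhibition
#'   (chemical inhibitor, siRNA, dominant negative), +1 for activation.
#' @param label optional free-text perturbagen description per component.
#' @return a \linkS4class{PerturbationPanel}.
#' @examples
#' PerturbationPanel(c("ERK", "JNK", "PKC"), sign = c(-1, -1, -1),
#'     label = c("PD98059", "SP600125", "BIM I"))
#' @export
PerturbationPanel <- function(component, sign, label = component) {
    new("PerturbationPanel",
        component = as.character(component),
        sign = as.integer(sign),
        label = as.character(label))
}

#' @rdname PerturbationPanel-class
#' @export
setMethod("componentNames", "PerturbationPanel", function(x) x@component)

#' @rdname PerturbationPanel-class
#' @export
setMethod("perturbationSigns", "PerturbationPanel",
    function(x) setNames(x@sign, x@component))

#' @rdname PerturbationPanel-class
#' @export
setMethod("perturbationLabels", "PerturbationPanel",
    function(x) setNames(x@label, x@component))

#' @rdname PerturbationPanel-class
#' @export
setMethod("length", "PerturbationPanel", function(x) length(x@component))

setMethod("show", "PerturbationPanel", function(object) {
    cat("PerturbationPanel with", length(object), "components\n")
    dir <- ifelse(object@sign < 0, "inhibition", "activation")
    for (i in seq_along(object@component))
        cat(sprintf("  %s (%s; %s)\n", object@component[i], dir[i],
            object@label[i]))
})
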