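#' Accessors for DctExperiment and SelectionReport
#'
#' `dctValues()` returns the numeric dCt matrix (miRNA x sample);
#' `flagImputed()`, `flagLowExpression()` and `flagMissing()` the matching
#' logical QC matrices. `panel()` returns the ordered candidate list of a
#' [SelectionReport-class] and `selectionTable()` its per-miRNA evaluation.
#'
#' @param x a `DctExperiment` or `SelectionReport`.
#' @return A matrix (dct/flag accessors), character vector (`panel`) or
#'   data.frame (`selectionTable`).
#' @name accessors
#' @aliases dctValues flagImputed flagLowExpression flagMissing panel
#'   selectionTable
NULL

#' @rdname accessors
#' @export
setGeneric("dctValues", function(x) standardGeneric("dctValues"))
#' @rdname accessors
#' @export
setGeneric("flagImputed", function(x) standardGeneric("flagImputed"))
#' @rdname accessors
#' @export
setGeneric("flagLowExpression",
           function(x) standardGeneric("flagLowExpression"))
#' @rdname accessors
#' @export
setGeneric("flagMissing", function(x) standardGeneric("flagMissing"))
#' @rdname accessors
#' @export
setGeneric("panel", function(x) standardGeneric("panel"))
#' @rdname accessors
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' @rdname accessors
#' @export
setMethod("dctValues", "DctExperiment",
          function(x) assay(x, "dct"))
#' @rdname accessors
#' @export
setMethod("flagImputed", "DctExperiment",
          function(x) assay(x, "imputed"))
#' @rdname accessors
#' @export
setMethod("flagLowExpression", "DctExperiment",
          function(x) assay(x, "lowExpression"))
#' @rdname accessors
#' @export
setMethod("flagMissing", "DctExperiment",
          function(x) assay(x, "missing"))
#' @rdname accessors
#' @export
setMethod("panel", "SelectionReport", function(x) x@panel)
#' @rdname accessors
#' @export
setMethod("selectionTable", "SelectionReport", function(x) x@table)

setMethod("show", "DctExperiment", function(object) {
    cat("DctExperiment:", nrow(object), "miRNAs x", ncol(object),
        "samples\n")
    cd <- colData(object)
    tab <- table(factor(cd$cohort, levels = .COHORTS),
                 factor(cd$timepoint, levels = .TIMEPOINTS))
    print(tab)
    cat(sprintf("cells imputed: %d | low-expression: %d | missing: %d\n",
                sum(assay(object, "imputed")),
                sum(assay(object, "lowExpression")),
                sum(assay(object, "missing"))))
    invisible(object)
})

setMethod("show", "SelectionReport", function(object) {
    cat("SelectionReport:", nrow(object@table), "miRNAs evaluated,",
        length(object@panel), "on the panel\n")
    if (length(object@panel))
        cat("panel:", paste(utils::head(object@panel, 10), collapse = ", "),
            if (length(object@panel) > 10) "..." else "", "\n")
    invisible(object)
})
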