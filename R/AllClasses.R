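#' @import methods
NULL

.STAGES <- c("raw", "blank_filtered", "mtic", "log", "pareto")

#' FeatureTable: a sample-by-feature intensity matrix with a processing stage
#'
#' The central container of the pipeline. Rows are samples, columns are
#' metabolite features; values are peak-height intensities (arbitrary units)
#' at stage \code{"raw"}, and transformed quantities at later stages. The
#' stage tag advances monotonically through
#' \code{raw -> blank_filtered -> mtic -> log -> pareto}; each processing
#' operation rejects tables at a later stage than it expects, so a table can
#' never be normalized or scaled twice by accident.
#'
#' For \code{stage = "pareto"} the per-feature centering constants and
#' scaling divisors are retained in the \code{paretoCenter}/\code{paretoScale}
#' slots so that downstream group means can be reported back on the
#' log(value + 1) scale.
#'
#' @slot values numeric matrix, samples x features, with unique dimnames.
#' @slot stage character scalar, one of raw, blank_filtered, mtic, log, pareto.
#' @slot paretoCenter,paretoScale per-feature affine constants recorded when
#'   Pareto scaling is applied (empty otherwise).
#'
#' @aliases FeatureTable
#' @exportClass FeatureTable
setClass("FeatureTable",
    representation(
        values = "matrix",
        stage = "character",
        paretoCenter = "numeric",
        paretoScale = "numeric"
    ),
    prototype(stage = "raw", paretoCenter = numeric(0), paretoScale = numeric(0))
)

setValidity("FeatureTable", function(object) {
    v <- object@values
    msg <- character(0)
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if ((nrow(v) > 0 && is.null(rownames(v))) ||
        (ncol(v) > 0 && is.null(colnames(v))))
        msg <- c(msg, "'values' must carry sample ids (rownames) and feature ids (colnames)")
    else {
        if (anyDuplicated(rownames(v))) msg <- c(msg, "sample ids must be unique")
        if (anyDuplicated(colnames(v))) msg <- c(msg, "feature ids must be unique")
    }
    if (length(object@stage) != 1L || !object@stage %in% .STAGES)
        msg <- c(msg, sprintf("'stage' must be one of: %s", paste(.STAGES, collapse = ", ")))
    if (anyNA(v))
        msg <- c(msg, "missing values are not allowed at any stage (imputation is explicit)")
    if (identical(object@stage, "raw") && length(v) && min(v) < 0)
        msg <- c(msg, "raw intensities must be non-negative")
    if (identical(object@stage, "pareto")) {
        if (length(object@paretoCenter) != ncol(v) || length(object@paretoScale) != ncol(v))
            msg <- c(msg, "pareto stage requires per-feature center and scale slots")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids).
#' @param stage processing-stage tag; new tables are almost always
#'   \code{"raw"}.
#' @param paretoCenter,paretoScale per-feature affine constants; only
#'   meaningful at stage \code{"pareto"} and normally filled in by
#'   \code{\link{paretoScale}}.
#' @return A \code{FeatureTable} object.
#' @examples
#' m <- matrix(rlnorm(12), 3, 4,
#'     dimnames = list(paste0("S", 1:3), paste0("M", 1:4)))
#' ft <- FeatureTable(m)
#' stage(ft)
#' @export
FeatureTable <- function(values, stage = "raw",
                         paretoCenter = numeric(0), paretoScale = numeric(0)) {
    new("FeatureTable", values = values, stage = stage,
        paretoCenter = paretoCenter, paretoScale = paretoScale)
}

#' @describeIn FeatureTable-accessors intensity matrix (samples x features)
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @describeIn FeatureTable-accessors processing-stage tag
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @describeIn FeatureTable-accessors sample identifiers
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @describeIn FeatureTable-accessors feature identifiers
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' Accessors for FeatureTable
#'
#' @param x a \code{FeatureTable}.
#' @name FeatureTable-accessors
#' @aliases intensities stage sampleIds featureIds
NULL

#' @rdname FeatureTable-accessors
#' @export
setMethod("intensities", "FeatureTable", function(x) x@values)

#' @rdname FeatureTable-accessors
#' @export
setMethod("stage", "FeatureTable", function(x) x@stage)

#' @rdname FeatureTable-accessors
#' @export
setMethod("sampleIds", "FeatureTable", function(x) rownames(x@values))

#' @rdname FeatureTable-accessors
#' @export
setMethod("featureIds", "FeatureTable", function(x) colnames(x@values))

setMethod("show", "FeatureTable", function(object) {
    cat(sprintf("FeatureTable: %d samples x %d features [stage: %s]\n",
        nrow(object@values), ncol(object@values), object@stage))
})

#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))

#' Subset a FeatureTable by samples (i) and/or features (j)
#'
#' Subsetting keeps the stage tag and, at stage \code{"pareto"}, the matching
#' slice of the stored centering/scaling constants.
#'
#' @param x a \code{FeatureTable}
#' @param i sample index; @param j feature index; @param drop ignored
#' @param ... ignored
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@values))
    if (missing(j)) j <- seq_len(ncol(x@values))
    pc <- x@paretoCenter
    ps <- x@paretoScale
    if (length(pc)) { pc <- pc[j]; ps <- ps[j] }
    new("FeatureTable", values = x@values[i, j, drop = FALSE], stage = x@stage,
        paretoCenter = pc, paretoScale = ps)
})

# stage gating used by the preprocessing operations
.check_stage <- function(table, allowed, op) {
    if (!stage(table) %in% allowed)
        stop(sprintf("%s() expects a table at stage %s, got '%s' (stages advance raw -> blank_filtered -> mtic -> log -> pareto)",
            op, paste(sQuote(allowed), collapse = "/"), stage(table)), call. = FALSE)
    invisible(TRUE)
}

#' NetworkModel: matrices of a weighted metabolite sub-network
#'
#' Bundle of the matrices produced by weighted sub-network analysis (WSNA):
#' the pairwise Pearson correlation \code{r}, the signed soft-power adjacency
#' \code{a} (\code{sign(r) * |r|^beta}, entries with \code{|r| < tau} set to
#' zero, zero diagonal), per-feature connectivity \code{k = rowSums(|a|)},
#' the topological overlap matrix \code{tom}, and the max-normalized TOM
#' dissimilarity \code{diss} used for module detection.
#'
#' @slot correlation,adjacency,tom,diss symmetric feature x feature matrices
#' @slot connectivity per-feature connectivity
#' @slot beta soft-threshold power; @slot tau hard threshold on |r|
#' @exportClass NetworkModel
setClass("NetworkModel",
    representation(
        correlation = "matrix", adjacency = "matrix",
        connectivity = "numeric", tom = "matrix", diss = "matrix",
        beta = "numeric", tau = "numeric"
    )
)

setValidity("NetworkModel", function(object) {
    msg <- character(0)
    for (nm in c("correlation", "adjacency", "tom", "diss")) {
        m <- slot(object, nm)
        if (!isSymmetric(unname(m), tol = 1e-8))
            msg <- c(msg, sprintf("'%s' must be symmetric", nm))
    }
    if (any(abs(object@adjacency) > 1 + 1e-12))
        msg <- c(msg, "adjacency entries must lie in [-1, 1]")
    if (length(object@diss) && max(abs(diag(object@diss))) > 1e-12)
        msg <- c(msg, "dissimilarity diagonal must be zero")
    if (any(object@tom < -1e-12) || any(object@tom > 1 + 1e-12))
        msg <- c(msg, "TOM entries must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "NetworkModel", function(object) {
    cat(sprintf("NetworkModel: %d features (beta = %g, tau = %g)\n",
        nrow(object@correlation), object@beta, object@tau))
    cat(sprintf("  connectivity: median %.3f, max %.3f\n",
        stats::median(object@connectivity), max(object@connectivity)))
})

#' ModuleSet: module labels and eigenmetabolite summaries
#'
#' @slot labels named integer vector, feature -> module id (1..K, labels
#'   ordered by decreasing module size)
#' @slot eigenmetabolites samples x K matrix of unit-norm first-PC score
#'   vectors, each oriented so its mean correlation with member features is
#'   positive
#' @slot varExplained fraction of member variance captured per module
#' @slot orientationSign the sign (+1/-1) applied to each raw PC to reach the
#'   reported orientation
#' @exportClass ModuleSet
setClass("ModuleSet",
    representation(
        labels = "integer", eigenmetabolites = "matrix",
        varExplained = "numeric", orientationSign = "numeric"
    )
)

setValidity("ModuleSet", function(object) {
    msg <- character(0)
    k <- max(object@labels)
    if (is.null(names(object@labels)))
        msg <- c(msg, "labels must be named by feature id")
    if (ncol(object@eigenmetabolites) != k)
        msg <- c(msg, "one eigenmetabolite column per module required")
    if (any(object@varExplained > 1 + 1e-8) || any(object@varExplained < 0))
        msg <- c(msg, "varExplained must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ModuleSet", function(object) {
    sz <- table(object@labels)
    cat(sprintf("ModuleSet: %d modules over %d features\n",
        length(sz), length(object@labels)))
    cat("  sizes:", paste(as.integer(sz), collapse = ", "), "\n")
    cat("  var explained:", paste(sprintf("%.2f", object@varExplained), collapse = ", "), "\n")
})

#' @describeIn ModuleSet-accessors per-feature module labels
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @describeIn ModuleSet-accessors samples x modules eigenmetabolite matrix
#' @export
setGeneric("eigenmetaboliteScores", function(x) standardGeneric("eigenmetaboliteScores"))

#' @describeIn ModuleSet-accessors per-module variance explained
#' @export
setGeneric("varExplained", function(x) standardGeneric("varExplained"))

#' Accessors for ModuleSet
#' @param x a \code{ModuleSet}
#' @name ModuleSet-accessors
#' @aliases moduleLabels eigenmetaboliteScores varExplained
NULL

#' @rdname ModuleSet-accessors
#' @export
setMethod("moduleLabels", "ModuleSet", function(x) x@labels)

#' @rdname ModuleSet-accessors
#' @export
setMethod("eigenmetaboliteScores", "ModuleSet", function(x) x@eigenmetabolites)

#' @rdname ModuleSet-accessors
#' @export
setMethod("varExplained", "ModuleSet", function(x) x@varExplained)
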