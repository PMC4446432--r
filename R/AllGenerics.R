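#' @import methods
NULL

#' @rdname LaneProfile-class
#' @param x An object.
#' @export
setGeneric("migration", function(x) standardGeneric("migration"))

#' @rdname LaneProfile-class
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname LaneProfile-class
#' @export
setGeneric("laneLabel", function(x) standardGeneric("laneLabel"))

#' @rdname LaneProfile-class
#' @export
setGeneric("enzymeTreated", function(x) standardGeneric("enzymeTreated"))

#' @rdname LaneProfile-class
#' @export
setGeneric("timeMin", function(x) standardGeneric("timeMin"))

#' @rdname MigrationMap-class
#' @param map A \code{MigrationMap}.
#' @param migration Numeric vector of migration coordinates.
#' @export
setGeneric("migrationToLength", function(map, migration)
    standardGeneric("migrationToLength"))

#' @rdname RepairCurve-class
#' @export
setGeneric("timesMin", function(x) standardGeneric("timesMin"))

#' @rdname RepairCurve-class
#' @export
setGeneric("repairPercent", function(x) standardGeneric("repairPercent"))

#' @rdname RepairCurve-class
#' @export
setGeneric("lesionsPerKb", function(x) standardGeneric("lesionsPerKb"))

#' @rdname RepairCurve-class
#' @export
setGeneric("initialPerKb", function(x) standardGeneric("initialPerKb"))

#' @rdname THalfProfile-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname THalfProfile-class
#' @export
setGeneric("tHalf", function(x) standardGeneric("tHalf"))

#' @rdname THalfProfile-class
#' @export
setGeneric("isCensored", function(x) standardGeneric("isCensored"))

#' @rdname THalfProfile-class
#' @export
setGeneric("smoothedTHalf", function(x) standardGeneric("smoothedTHalf"))

#' @rdname THalfProfile-class
#' @export
setGeneric("nucleosomeLabel", function(x) standardGeneric("nucleosomeLabel"))
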