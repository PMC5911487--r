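#' @name FollowerScan-generics
#' @title Accessor generics used across FollowerScan classes
#' @param x an object
#' @param ... passed to methods
#' @keywords internal
NULL

#' @rdname FollowerScan-generics
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("stimSchedule", function(x) standardGeneric("stimSchedule"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("patchedCell", function(x) standardGeneric("patchedCell"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("cellPositions", function(x) standardGeneric("cellPositions"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("onsets", function(x) standardGeneric("onsets"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("meanZ", function(x) standardGeneric("meanZ"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("followerLabels", function(x) standardGeneric("followerLabels"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("percentFollowers", function(x, ...) standardGeneric("percentFollowers"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname FollowerScan-generics
#' @export
setGeneric("kernel", function(x) standardGeneric("kernel"))
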