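#' Accuracy of a confusion matrix
#'
#' `(tp + tn) / (tp + fn + tn + fp)`, with the chaos class positive.
#'
#' @param object a [ConfusionCounts-class] (or something coercible).
#' @return numeric scalar in `[0, 1]`.
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' @rdname LabelledSegmentSet-class
#' @param object a `LabelledSegmentSet`.
#' @export
setGeneric("segmentValues", function(object) standardGeneric("segmentValues"))

#' @rdname LabelledSegmentSet-class
#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))

#' @rdname LabelledSegmentSet-class
#' @export
setGeneric("segmentSource", function(object) standardGeneric("segmentSource"))

#' Number of items in a container
#'
#' @param object a package container (segment set, signal set, manifest).
#' @return integer count.
#' @export
setGeneric("nItems", function(object) standardGeneric("nItems"))

#' @rdname Trajectory-class
#' @param object a `Trajectory`.
#' @export
setGeneric("trajectoryValues", function(object) standardGeneric("trajectoryValues"))

#' @rdname Trajectory-class
#' @export
setGeneric("trajectoryTimes", function(object) standardGeneric("trajectoryTimes"))
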