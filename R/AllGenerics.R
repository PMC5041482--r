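# Generics and accessors.  Slot access from user code goes through these.

#' @rdname MotifSet-class
#' @param x a MotifSet
#' @export
setGeneric("motifs", function(x) standardGeneric("motifs"))

#' @rdname MotifSet-class
#' @export
setMethod("motifs", "MotifSet", function(x) x@motifs)

#' @rdname MotifSet-class
#' @export
setGeneric("protein", function(x) standardGeneric("protein"))

#' @rdname MotifSet-class
#' @export
setMethod("protein", "MotifSet", function(x) x@protein)

#' @rdname BinnedProfile-class
#' @param x a BinnedProfile
#' @export
setGeneric("profileBins", function(x) standardGeneric("profileBins"))

#' @rdname BinnedProfile-class
#' @export
setMethod("profileBins", "BinnedProfile", function(x) x@bins)

#' @rdname BinnedProfile-class
#' @export
setGeneric("profileAnchor", function(x) standardGeneric("profileAnchor"))

#' @rdname BinnedProfile-class
#' @export
setMethod("profileAnchor", "BinnedProfile",
          function(x) c(anchor = x@anchor, direction = x@direction))

#' @rdname CaiWeights-class
#' @param x a CaiWeights object
#' @export
setGeneric("adaptiveness", function(x) standardGeneric("adaptiveness"))

#' @rdname CaiWeights-class
#' @export
setMethod("adaptiveness", "CaiWeights", function(x) x@weights)

#' @rdname SyntheticDataset-class
#' @param x a SyntheticDataset
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname SyntheticDataset-class
#' @export
setMethod("genomeSeq", "SyntheticDataset", function(x) x@genome)

#' @rdname SyntheticDataset-class
#' @export
setGeneric("transcriptAnnotation",
           function(x) standardGeneric("transcriptAnnotation"))

#' @rdname SyntheticDataset-class
#' @export
setMethod("transcriptAnnotation", "SyntheticDataset",
          function(x) x@transcripts)

#' @rdname SyntheticDataset-class
#' @export
setGeneric("expressionTrack", function(x) standardGeneric("expressionTrack"))

#' @rdname SyntheticDataset-class
#' @export
setMethod("expressionTrack", "SyntheticDataset", function(x) x@expression)

#' @rdname SyntheticDataset-class
#' @export
setGeneric("readMidpoints", function(x) standardGeneric("readMidpoints"))

#' @rdname SyntheticDataset-class
#' @export
setMethod("readMidpoints", "SyntheticDataset", function(x) x@midpoints)

#' @rdname SyntheticDataset-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname SyntheticDataset-class
#' @export
setMethod("groundTruth", "SyntheticDataset", function(x) x@truth)

#' @rdname SyntheticDataset-class
#' @export
setGeneric("generatorSettings",
           function(x) standardGeneric("generatorSettings"))

#' @rdname SyntheticDataset-class
#' @export
setMethod("generatorSettings", "SyntheticDataset", function(x) x@config)
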