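#' Accessors for package classes
#'
#' Standard accessor generics; use these rather than `@` slot access.
#'
#' @param x a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("ldr", function(x) standardGeneric("ldr"))
#' @rdname accessors
#' @export
setGeneric("probeId", function(x) standardGeneric("probeId"))
#' @rdname accessors
#' @export
setGeneric("probeChrom", function(x) standardGeneric("probeChrom"))
#' @rdname accessors
#' @export
setGeneric("probePos", function(x) standardGeneric("probePos"))
#' @rdname accessors
#' @export
setGeneric("probeGene", function(x) standardGeneric("probeGene"))
#' @rdname accessors
#' @export
setGeneric("omicsLayer", function(x) standardGeneric("omicsLayer"))
#' @rdname accessors
#' @export
setGeneric("cisRecords", function(x) standardGeneric("cisRecords"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypePanel", function(x) x@sampleIds)
#' @rdname accessors
#' @export
setMethod("snpInfo", "GenotypePanel", function(x) x@snps)
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypePanel", function(x) x@dosages)
#' @rdname accessors
#' @export
setMethod("snpIds", "GenotypePanel", function(x) x@snps$snp)

#' @rdname accessors
#' @export
setMethod("snpIds", "LDMatrix", function(x) x@snpIds)
#' @rdname accessors
#' @export
setMethod("ldr", "LDMatrix", function(x) x@r)

#' @rdname accessors
#' @export
setMethod("probeId", "QtlProbe", function(x) x@probeId)
#' @rdname accessors
#' @export
setMethod("probeChrom", "QtlProbe", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("probePos", "QtlProbe", function(x) x@pos)
#' @rdname accessors
#' @export
setMethod("probeGene", "QtlProbe", function(x) x@gene)
#' @rdname accessors
#' @export
setMethod("omicsLayer", "QtlProbe", function(x) x@layer)
#' @rdname accessors
#' @export
setMethod("cisRecords", "QtlProbe", function(x) x@cisRecords)
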